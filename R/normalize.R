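#' Normalized structure factors (E-values)
#'
#' E^2(h) = F^2(h) / (epsilon_h <F^2/epsilon>_shell), where the average
#' runs over an equal-population resolution shell in 1/d^2 and epsilon is
#' the reflection's statistical weight. Shell-wise normalization removes
#' the resolution-dependent falloff so that <E^2> = 1 both overall and in
#' every shell.
#'
#' @param refs A `reflection_set` with amplitudes present.
#' @param n_shells Number of equal-population resolution shells (default
#'   10). Automatically reduced, with a warning, if shells would hold
#'   fewer than 3 reflections.
#' @param use Which amplitude column to normalize: `"f_obs"` (default,
#'   falling back to `f_true` when observations are absent) or `"f_true"`.
#' @return The reflection set with column `e_value` filled.
#' @export
normalize_E <- function(refs, n_shells = 10, use = c("f_obs", "f_true")) {
  use <- match.arg(use)
  f <- refs[[use]]
  if (is.null(f)) f <- refs$f_true
  if (is.null(f)) stop("no amplitudes present; run calc_structure_factors() first")
  n <- length(f)
  if (n == 0) { refs$e_value <- numeric(0); return(refs) }
  max_shells <- max(1L, n %/% 3L)
  if (n_shells > max_shells) {
    warning("reducing n_shells from ", n_shells, " to ", max_shells,
            " (too few reflections per shell)")
    n_shells <- max_shells
  }
  s2 <- 1 / refs$d^2
  shell <- ceiling(rank(s2, ties.method = "first") * n_shells / n)
  y <- f^2 / refs$epsilon
  mean_shell <- ave(y, shell, FUN = mean)
  if (any(mean_shell <= 0)) {
    # degenerate all-zero shell: fall back to the global mean
    g <- mean(y)
    if (g <= 0) stop("all amplitudes are zero; cannot normalize")
    mean_shell[mean_shell <= 0] <- g
  }
  refs$e_value <- sqrt(y / mean_shell)
  refs
}

#' Amplitude agreement factor Rf
#'
#' Rf = sum | |F_obs| - s |F_calc| | / sum |F_obs|, with `s` an optional
#' least-squares scale factor between the two sets (on by default, since
#' compared amplitude sets are generally on different scales).
#'
#' @param f_obs,f_calc Equal-length non-negative amplitude vectors.
#' @param scale Apply the least-squares scale `s = sum(Fo Fc)/sum(Fc^2)`?
#' @return Rf as a fraction (0 for identical sets).
#' @examples
#' r_factor(c(1, 2, 3), c(2, 4, 6)) # 0: scale absorbs the factor of 2
#' @export
r_factor <- function(f_obs, f_calc, scale = TRUE) {
  if (length(f_obs) != length(f_calc))
    stop("f_obs and f_calc must have equal length")
  if (length(f_obs) == 0 || sum(f_obs) <= 0)
    stop("observed amplitudes are all zero")
  s <- if (scale && sum(f_calc^2) > 0) sum(f_obs * f_calc) / sum(f_calc^2) else 1
  sum(abs(f_obs - s * f_calc)) / sum(f_obs)
}
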