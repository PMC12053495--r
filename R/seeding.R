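#' Phase sampling grid
#'
#' The coarse angular grids used to discretize general-reflection phases:
#' k equally spaced points 360 j / k (j = 0..k-1) on the phase circle, for
#' k in {2, 3, 4, 6}.
#'
#' @param k Number of sampling points: 2, 3, 4 or 6.
#' @return Object of class `sampling_grid` with elements `k` and `values`
#'   (degrees, ascending from 0).
#' @examples
#' sampling_grid(4)$values # 0 90 180 270
#' @export
sampling_grid <- function(k) {
  k <- as.integer(k)
  if (!k %in% c(2L, 3L, 4L, 6L))
    stop("sampling density k must be one of 2, 3, 4, 6")
  structure(list(k = k, values = 360 * (0:(k - 1)) / k),
            class = "sampling_grid")
}

#' @export
print.sampling_grid <- function(x, ...) {
  cat(sprintf("Phase sampling grid: k = %d, values {%s} deg\n",
              x$k, paste(x$values, collapse = ", ")))
  invisible(x)
}

#' Discretize phases onto a sampling grid
#'
#' Each phase is replaced by the nearest grid value along the phase
#' circle. Exact ties (halfway between two grid points) break toward the
#' smaller grid angle, so the result is deterministic.
#'
#' @param phi Phases in degrees (any real values; reduced mod 360).
#' @param grid A [sampling_grid()] or an integer k.
#' @return Discretized phases in degrees, each a member of `grid$values`;
#'   the circular distance to the input never exceeds 180/k.
#' @examples
#' discretize_phase(c(100, 350, 45), sampling_grid(4)) # 90 0 0
#' @export
discretize_phase <- function(phi, grid) {
  if (!inherits(grid, "sampling_grid")) grid <- sampling_grid(grid)
  phi <- phi %% 360
  dist <- abs(((outer(phi, grid$values, `-`) + 180) %% 360) - 180)
  grid$values[max.col(-dist, ties.method = "first")]
}

circular_diff <- function(a, b) {
  d <- abs(a - b) %% 360
  pmin(d, 360 - d)
}

#' Mean phase error
#'
#' Unweighted mean of the circular difference min(|dphi|, 360 - |dphi|)
#' between two phase sets over all symmetry-independent reflections;
#' lies in \[0, 180\] degrees. Random phases give 90 degrees on average.
#'
#' @param phi Current phases in degrees (or a `phase_assignment`, whose
#'   discretized phases `phi_d` are used).
#' @param phi_true Reference (true) phases in degrees.
#' @return MPE in degrees.
#' @examples
#' mean_phase_error(350, 10) # 20
#' @export
mean_phase_error <- function(phi, phi_true) {
  if (inherits(phi, "phase_assignment")) phi <- phi$phi_d
  if (length(phi) != length(phi_true)) stop("phase vectors differ in length")
  if (length(phi) == 0) stop("empty phase set")
  mean(circular_diff(phi, phi_true))
}

#' Select seed reflections
#'
#' Five strategies for choosing the reflections that receive true
#' (discretized) phases:
#' \describe{
#'   \item{random}{uniformly at random among all reflections;}
#'   \item{hkl_sorted}{all reflections inside the cubic reciprocal-space
#'     box max(|h|,|k|,|l|) <= `h_max` (seed size is set by `h_max`, not
#'     by `perc_seed`);}
#'   \item{d_sorted}{from low to high resolution (largest d first);}
#'   \item{e_sorted}{from the largest E-value down;}
#'   \item{e_random}{uniformly at random among reflections with
#'     E > `e_threshold` (default 1.0).}
#' }
#' For all percentage-driven modes the seed size is exactly
#' `round(perc_seed * N_refl / 100)`. Random draws use R's global RNG
#' stream; call `set.seed()` upstream for reproducibility.
#'
#' @param refs A `reflection_set` (with `e_value` for the `e_*` modes).
#' @param mode One of `"random"`, `"hkl_sorted"`, `"d_sorted"`,
#'   `"e_sorted"`, `"e_random"`.
#' @param perc_seed Seed size as a percentage of N_refl, in \[0, 100\].
#' @param h_max Miller-index bound for `hkl_sorted`.
#' @param e_threshold E-value floor for `e_random` (default 1.0).
#' @return Logical seed mask of length `nrow(refs)`.
#' @export
select_seed <- function(refs, mode = c("random", "hkl_sorted", "d_sorted",
                                       "e_sorted", "e_random"),
                        perc_seed = NULL, h_max = NULL, e_threshold = 1.0) {
  mode <- match.arg(mode)
  n <- nrow(refs)
  mask <- rep(FALSE, n)
  if (mode == "hkl_sorted") {
    if (is.null(h_max)) stop("hkl_sorted mode requires h_max")
    return(pmax(abs(refs$h), abs(refs$k), abs(refs$l)) <= h_max)
  }
  if (is.null(perc_seed) || perc_seed < 0 || perc_seed > 100)
    stop("perc_seed must be given in [0, 100]")
  n_seed <- round(perc_seed * n / 100)
  if (n_seed == 0) return(mask)
  idx <- switch(mode,
    random = sample.int(n, n_seed),
    d_sorted = order(refs$d, decreasing = TRUE)[seq_len(n_seed)],
    e_sorted = {
      if (is.null(refs$e_value)) stop("e_sorted mode requires e_value; run normalize_E()")
      order(refs$e_value, decreasing = TRUE)[seq_len(n_seed)]
    },
    e_random = {
      if (is.null(refs$e_value)) stop("e_random mode requires e_value; run normalize_E()")
      pool <- which(refs$e_value > e_threshold)
      if (length(pool) < n_seed)
        stop(sprintf(
          "e_random: only %d reflections have E > %g (maximum Perc_seed %.1f%%)",
          length(pool), e_threshold, 100 * length(pool) / n))
      pool[sample.int(length(pool), n_seed)]
    })
  mask[idx] <- TRUE
  mask
}

#' Assign initial phases
#'
#' Implements the pre-processing step of the seeding protocol. Every
#' reflection first receives a random actual phase phi_a; it is then
#' discretized to phi_d on the chosen sampling grid. Seed reflections
#' receive the true phase as phi_a instead, so their phi_d is the
#' discretized truth; seed centric reflections keep the exact true value
#' (the restricted values are themselves grid points of the restricted
#' set). Non-seed centric reflections draw phi_d uniformly from their two
#' allowed values.
#'
#' @param refs A `reflection_set` with `phi_true` populated.
#' @param seed_mask Logical mask from [select_seed()].
#' @param grid A [sampling_grid()] or integer k.
#' @return Object of class `phase_assignment`: data frame with columns
#'   `phi_a`, `phi_d`, `seed`, plus attribute `grid`.
#' @export
assign_initial_phases <- function(refs, seed_mask, grid) {
  if (!inherits(grid, "sampling_grid")) grid <- sampling_grid(grid)
  if (is.null(refs$phi_true)) stop("phi_true missing; run calc_structure_factors()")
  n <- nrow(refs)
  stopifnot(length(seed_mask) == n)
  phi_a <- stats::runif(n, 0, 360)
  phi_a[seed_mask] <- refs$phi_true[seed_mask]
  phi_d <- discretize_phase(phi_a, grid)
  cen <- refs$centric
  # non-seed centric: random choice among the two allowed values
  ns_cen <- cen & !seed_mask
  if (any(ns_cen)) {
    pick <- sample(c(0, 180), sum(ns_cen), replace = TRUE)
    phi_d[ns_cen] <- (refs$phi_restrict[ns_cen] + pick) %% 360
    phi_a[ns_cen] <- phi_d[ns_cen]  # restricted phases only take two values
  }
  # seed centric: exact true value (phi_a and phi_d coincide)
  s_cen <- cen & seed_mask
  phi_d[s_cen] <- refs$phi_true[s_cen]
  out <- data.frame(phi_a = phi_a, phi_d = phi_d, seed = seed_mask)
  structure(out, class = c("phase_assignment", "data.frame"), grid = grid)
}

#' @export
print.phase_assignment <- function(x, ...) {
  g <- attr(x, "grid")
  cat(sprintf("Phase assignment: %d reflections, %d seed (%.1f%%), k = %d grid\n",
              nrow(x), sum(x$seed), 100 * mean(x$seed), g$k))
  invisible(x)
}
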