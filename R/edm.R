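#' EDM configuration
#'
#' Parameters of the dual-space phase extension and refinement engine.
#'
#' @param n_cycles Maximum number of EDM cycles (default 200).
#' @param keep_fraction Fraction of grid points retained by the density
#'   truncation (default 0.03, appropriate for small-molecule maps; use
#'   ~0.15 for protein-like maps).
#' @param free_lunch Extrapolate unmeasured reflections beyond the data
#'   resolution during recycling? Default `TRUE`.
#' @param extension_factor Resolution multiplier (< 1) for the free-lunch
#'   extrapolation shell: unmeasured lattice points with
#'   `d_min * extension_factor <= d < d_min` join the recycling. Default 0.8.
#' @param solved_mpe_threshold Final mean phase error (degrees) at or below
#'   which a run is declared solved. Default 45, midway between random
#'   phases (90) and excellent phases (< 20).
#' @param grid_oversampling Map grid spacing is at most
#'   `d_min / grid_oversampling` along each axis (default 3).
#' @param converge_tol Mean absolute phase change (degrees) under which,
#'   for 3 consecutive cycles, the iteration is declared converged and
#'   stopped early; set to 0 to always run the full `n_cycles`.
#' @return Object of class `edm_config`.
#' @export
edm_config <- function(n_cycles = 200, keep_fraction = 0.03,
                       free_lunch = TRUE, extension_factor = 0.8,
                       solved_mpe_threshold = 45, grid_oversampling = 3,
                       converge_tol = 0.05) {
  if (keep_fraction <= 0 || keep_fraction > 1)
    stop("keep_fraction must be in (0, 1]")
  if (extension_factor <= 0 || extension_factor > 1)
    stop("extension_factor must be in (0, 1]")
  if (n_cycles < 1) stop("n_cycles must be >= 1")
  structure(list(n_cycles = as.integer(n_cycles),
                 keep_fraction = keep_fraction,
                 free_lunch = isTRUE(free_lunch),
                 extension_factor = extension_factor,
                 solved_mpe_threshold = solved_mpe_threshold,
                 grid_oversampling = grid_oversampling,
                 converge_tol = converge_tol),
            class = "edm_config")
}

# smallest 2-3-5-7-smooth integer >= n (FFT-friendly grid dimension)
next_fft_friendly <- function(n) {
  n <- max(2L, as.integer(ceiling(n)))
  repeat {
    m <- n
    for (p in c(2L, 3L, 5L, 7L)) while (m %% p == 0L) m <- m %/% p
    if (m == 1L) return(n)
    n <- n + 1L
  }
}

#' Map grid shape for a resolution limit
#'
#' Smallest FFT-friendly grid with spacing at most `d_eff / oversampling`
#' along each cell axis (anti-aliasing for the truncation operator).
#'
#' @param cell A [unit_cell()].
#' @param d_eff Effective resolution in Angstrom (include the free-lunch
#'   extension if used).
#' @param oversampling Oversampling factor (default 3).
#' @return Integer vector of 3 grid dimensions.
#' @export
map_grid_shape <- function(cell, d_eff, oversampling = 3) {
  axes <- c(cell$a, cell$b, cell$c)
  vapply(axes, function(a) next_fft_friendly(oversampling * a / d_eff),
         integer(1))
}

# Precompute the symmetry + Friedel expansion of a reflection list onto a
# map grid: for expansion entry j, the grid linear index `idx`, source
# reflection `src`, phase sign `sgn` and phase offset `off` (degrees), so
# that the coefficient placed at idx is amp[src] exp(i (sgn phi[src] + off)).
map_expansion <- function(H, sg, grid_shape) {
  rots <- sg_rotations(sg)
  trans <- sg_translations(sg)
  n <- nrow(H)
  idx <- src <- sgn <- off <- vector("list", 2 * length(rots))
  for (s in seq_along(rots)) {
    Hs <- H %*% rots[[s]]
    os <- -360 * as.numeric(H %*% trans[[s]])
    i1 <- grid_linear_index(Hs, grid_shape)
    i2 <- grid_linear_index(-Hs, grid_shape)
    idx[[2 * s - 1]] <- i1; src[[2 * s - 1]] <- seq_len(n)
    sgn[[2 * s - 1]] <- rep(1, n);  off[[2 * s - 1]] <- os
    idx[[2 * s]] <- i2; src[[2 * s]] <- seq_len(n)
    sgn[[2 * s]] <- rep(-1, n); off[[2 * s]] <- -os
  }
  list(idx = unlist(idx), src = unlist(src),
       sgn = unlist(sgn), off = unlist(off))
}

grid_linear_index <- function(H, gs) {
  i1 <- H[, 1] %% gs[1]
  i2 <- H[, 2] %% gs[2]
  i3 <- H[, 3] %% gs[3]
  as.integer(i1 + gs[1] * (i2 + gs[2] * i3)) + 1L
}

#' Synthesize an electron-density map
#'
#' Fourier synthesis rho(x) = (1/V) sum_h F(h) exp(-2 pi i h . x) over the
#' full sphere, expanding the symmetry-unique reflections through all
#' space-group operators and Friedel mates; F(000) is omitted. The map is
#' real by construction (imaginary residue below 1e-8 of the map norm).
#'
#' @param refs A `reflection_set`.
#' @param phi Phases in degrees for each reflection (or a
#'   `phase_assignment`, whose `phi_d` is used).
#' @param grid_shape Integer triple from [map_grid_shape()]; computed
#'   automatically when `NULL`.
#' @param amplitudes Amplitude vector (default `f_obs`).
#' @return Object of class `density_map`: list with `values` (3D array),
#'   `grid_shape` and `cell`.
#' @export
synthesize_map <- function(refs, phi, grid_shape = NULL, amplitudes = NULL) {
  cell <- attr(refs, "cell")
  sg <- attr(refs, "spacegroup")
  if (inherits(phi, "phase_assignment")) phi <- phi$phi_d
  if (is.null(amplitudes)) amplitudes <- refs$f_obs
  if (is.null(amplitudes)) stop("no amplitudes available")
  if (is.null(grid_shape))
    grid_shape <- map_grid_shape(cell, attr(refs, "d_min"))
  check_grid_nyquist(refs, grid_shape)
  H <- hkl_matrix(refs)
  exp_tab <- map_expansion(H, sg, grid_shape)
  map_from_expansion(exp_tab, amplitudes, phi, grid_shape, cell)
}

check_grid_nyquist <- function(refs, grid_shape) {
  if (nrow(refs) == 0) return(invisible())
  hm <- c(max(abs(refs$h)), max(abs(refs$k)), max(abs(refs$l)))
  need <- 2L * hm + 1L
  if (any(grid_shape < need))
    stop("map grid ", paste(grid_shape, collapse = "x"),
         " too coarse for the reflection set; need at least ",
         paste(need, collapse = "x"))
}

map_from_expansion <- function(exp_tab, amplitudes, phi, grid_shape, cell) {
  Fg <- array(complex(real = 0), dim = grid_shape)
  rad <- (exp_tab$sgn * phi[exp_tab$src] + exp_tab$off) * pi / 180
  Fg[exp_tab$idx] <- amplitudes[exp_tab$src] * exp(1i * rad)
  rho <- stats::fft(Fg) / cell$volume
  structure(list(values = Re(rho), grid_shape = grid_shape, cell = cell,
                 imag_residue = max(abs(Im(rho))) /
                   max(max(abs(Re(rho))), .Machine$double.eps)),
            class = "density_map")
}

#' @export
print.density_map <- function(x, ...) {
  cat(sprintf("Density map: %s grid, rho in [%.3g, %.3g] e/A^3\n",
              paste(x$grid_shape, collapse = " x "),
              min(x$values), max(x$values)))
  invisible(x)
}

#' Density modification by truncation
#'
#' Enforces the atomistic hypothesis in direct space: all negative density
#' is set to zero, and only the top `keep_fraction` of grid points (by
#' density value) is retained; everything else is flattened to zero.
#'
#' @param map A `density_map`.
#' @param keep_fraction Fraction of grid points to retain, in (0, 1].
#' @return The modified `density_map`.
#' @export
modify_density <- function(map, keep_fraction) {
  if (keep_fraction <= 0 || keep_fraction > 1)
    stop("keep_fraction must be in (0, 1]")
  v <- as.vector(map$values)
  n_keep <- ceiling(keep_fraction * length(v))
  keep <- rep(FALSE, length(v))
  keep[order(v, decreasing = TRUE)[seq_len(n_keep)]] <- TRUE
  v[!keep] <- 0
  v[v < 0] <- 0
  map$values <- array(v, dim = map$grid_shape)
  map
}

#' Structure factors from a map
#'
#' Inverse step of the dual-space cycle: forward-transforms the (modified)
#' map and reads calculated amplitudes and phases at the symmetry-unique
#' reflection positions. Centric reflections are snapped to the nearest
#' allowed restricted phase value.
#'
#' @param map A `density_map`.
#' @param refs A `reflection_set` (same cell/space group as the map).
#' @return Data frame with columns `phi` (degrees, \[0,360)) and `f_calc`.
#' @export
recompute_phases <- function(map, refs) {
  check_grid_nyquist(refs, map$grid_shape)
  Fg <- stats::fft(map$values, inverse = TRUE) *
    map$cell$volume / prod(map$grid_shape)
  idx <- grid_linear_index(hkl_matrix(refs), map$grid_shape)
  Fc <- Fg[idx]
  phi <- (Arg(Fc) * 180 / pi) %% 360
  phi <- snap_centric(phi, refs)
  data.frame(phi = phi, f_calc = Mod(Fc))
}

snap_centric <- function(phi, refs) {
  cen <- which(refs$centric)
  if (length(cen)) {
    p0 <- refs$phi_restrict[cen]
    d0 <- circular_diff(phi[cen], p0)
    d1 <- circular_diff(phi[cen], p0 + 180)
    phi[cen] <- ifelse(d0 <= d1, p0, (p0 + 180) %% 360)
  }
  phi
}

#' Free-lunch extension shell
#'
#' Unmeasured lattice points between `d_min * extension_factor` and the
#' measured resolution limit `d_min`. During EDM recycling these receive
#' calculated amplitudes and phases from the current map; they are never
#' counted in MPE or Rf.
#'
#' @param refs Measured `reflection_set`.
#' @param extension_factor Multiplier in (0, 1]; 1 adds nothing.
#' @return A `reflection_set` of the extension reflections only.
#' @export
free_lunch_extend <- function(refs, extension_factor) {
  cell <- attr(refs, "cell"); sg <- attr(refs, "spacegroup")
  d_min <- attr(refs, "d_min")
  if (extension_factor >= 1) return(refs[0, ])
  ext <- suppressWarnings(
    unique_reflections(cell, sg, d_min * extension_factor,
                       attr(refs, "wavelength")))
  key <- function(r) paste(r$h, r$k, r$l)
  ext <- ext[!key(ext) %in% key(refs), ]
  ext
}

#' Run dual-space phase extension and refinement
#'
#' Iterates synthesize -> truncate -> back-transform cycles: the map is
#' computed from current phases with measured amplitudes, modified by
#' positivity + top-density truncation, and back-transformed; measured
#' reflections keep |F_obs| and adopt the new (continuous) phases, while
#' free-lunch reflections adopt both calculated amplitude and phase. The
#' run stops early on convergence (phases stationary) or divergence (Rf
#' rising for 10 consecutive cycles).
#'
#' @param refs A `reflection_set` with `f_obs` (and `phi_true` if MPE
#'   tracking and the solved verdict are wanted).
#' @param initial Initial phases: a `phase_assignment` or a numeric vector
#'   of degrees.
#' @param config An [edm_config()].
#' @return Object of class `edm_result`: list with `phi` (final phases,
#'   degrees), `f_calc`, `trace` (per-cycle `mpe`, `rf`, `map_cor`),
#'   `solved`, `mpe_initial`, `mpe_final`, `n_cycles_run`, `stopped` (one
#'   of "max_cycles", "converged", "diverged") and `config`.
#' @export
run_edm <- function(refs, initial, config = edm_config()) {
  stopifnot(inherits(refs, "reflection_set"))
  if (is.null(refs$f_obs)) stop("f_obs missing on the reflection set")
  phi <- if (inherits(initial, "phase_assignment")) initial$phi_d
         else as.numeric(initial)
  if (length(phi) != nrow(refs)) stop("initial phases have wrong length")
  cell <- attr(refs, "cell"); sg <- attr(refs, "spacegroup")
  d_min <- attr(refs, "d_min")
  have_truth <- !is.null(refs$phi_true)
  n_meas <- nrow(refs)

  ext <- if (config$free_lunch)
    free_lunch_extend(refs, config$extension_factor) else refs[0, ]
  n_ext <- nrow(ext)
  d_eff <- if (n_ext > 0) d_min * config$extension_factor else d_min
  gs <- map_grid_shape(cell, d_eff, config$grid_oversampling)
  H_all <- rbind(hkl_matrix(refs), hkl_matrix(ext))
  exp_tab <- map_expansion(H_all, sg, gs)
  idx0 <- grid_linear_index(H_all, gs)
  cen_all <- c(refs$centric, ext$centric)
  p0_all <- c(refs$phi_restrict, ext$phi_restrict)

  amp <- c(refs$f_obs, rep(0, n_ext))
  phi_all <- c(phi, rep(0, n_ext))
  mpe0 <- if (have_truth) mean_phase_error(phi, refs$phi_true) else NA_real_

  truth_map <- if (have_truth)
    as.vector(map_from_expansion(map_expansion(hkl_matrix(refs), sg, gs),
                                 refs$f_true, refs$phi_true, gs, cell)$values)
  else NULL

  trace <- data.frame(cycle = integer(0), mpe = numeric(0), rf = numeric(0),
                      map_cor = numeric(0))
  rf_up <- 0L; conv_n <- 0L; rf_prev <- Inf
  stopped <- "max_cycles"
  vfac <- cell$volume / prod(gs)
  for (cyc in seq_len(config$n_cycles)) {
    map <- map_from_expansion(exp_tab, amp, phi_all, gs, cell)
    # keep_fraction = 1 disables the modification entirely (pure Fourier
    # recycling), so the dual-space cycle is exactly the identity there
    if (config$keep_fraction < 1)
      map <- modify_density(map, config$keep_fraction)
    Fg <- stats::fft(map$values, inverse = TRUE) * vfac
    Fc <- Fg[idx0]
    phi_new <- (Arg(Fc) * 180 / pi) %% 360
    cen <- which(cen_all)
    if (length(cen)) {
      d0 <- circular_diff(phi_new[cen], p0_all[cen])
      d1 <- circular_diff(phi_new[cen], p0_all[cen] + 180)
      phi_new[cen] <- ifelse(d0 <= d1, p0_all[cen],
                             (p0_all[cen] + 180) %% 360)
    }
    f_calc <- Mod(Fc)
    shift <- mean(circular_diff(phi_new[seq_len(n_meas)],
                                phi_all[seq_len(n_meas)]))
    phi_all <- phi_new
    if (n_ext > 0) amp[n_meas + seq_len(n_ext)] <- f_calc[n_meas + seq_len(n_ext)]
    rf <- r_factor(refs$f_obs, f_calc[seq_len(n_meas)])
    mpe <- if (have_truth)
      mean_phase_error(phi_all[seq_len(n_meas)], refs$phi_true) else NA_real_
    mcor <- if (have_truth)
      stats::cor(as.vector(map$values), truth_map) else NA_real_
    trace <- rbind(trace, data.frame(cycle = cyc, mpe = mpe, rf = rf,
                                     map_cor = mcor))
    rf_up <- if (rf > rf_prev + 1e-3) rf_up + 1L else 0L
    rf_prev <- rf
    if (rf_up >= 10L) { stopped <- "diverged"; break }
    conv_n <- if (shift < config$converge_tol && config$converge_tol > 0)
      conv_n + 1L else 0L
    if (conv_n >= 3L) { stopped <- "converged"; break }
  }
  mpe_final <- if (have_truth)
    mean_phase_error(phi_all[seq_len(n_meas)], refs$phi_true) else NA_real_
  solved <- if (stopped == "diverged") FALSE
            else isTRUE(mpe_final <= config$solved_mpe_threshold)
  structure(list(
    phi = phi_all[seq_len(n_meas)], f_calc = f_calc[seq_len(n_meas)],
    trace = trace, solved = solved, mpe_initial = mpe0,
    mpe_final = mpe_final, rf_final = rf_prev,
    n_cycles_run = nrow(trace), stopped = stopped, config = config),
    class = "edm_result")
}

#' @export
print.edm_result <- function(x, ...) {
  cat(sprintf(
    "EDM phasing run: %d cycles (%s), MPE %.1f -> %.1f deg, Rf %.3f, %s\n",
    x$n_cycles_run, x$stopped,
    x$mpe_initial, x$mpe_final, x$rf_final,
    if (isTRUE(x$solved)) "SOLVED" else "not solved"))
  invisible(x)
}

#' @export
summary.edm_result <- function(object, ...) {
  cat("Dual-space phase extension and refinement\n")
  print(object)
  cat(sprintf("  keep_fraction %.3g, free lunch %s, solved threshold %.0f deg\n",
              object$config$keep_fraction,
              if (object$config$free_lunch) "on" else "off",
              object$config$solved_mpe_threshold))
  tr <- object$trace
  show <- tr[unique(pmin(nrow(tr), c(1, 2, 5, 10, 20, 50, 100, nrow(tr)))), ]
  print(show, row.names = FALSE)
  invisible(object)
}

#' @export
plot.edm_result <- function(x, ...) {
  tr <- x$trace
  op <- graphics::par(mar = c(4, 4, 2, 4))
  on.exit(graphics::par(op))
  graphics::plot(tr$cycle, tr$mpe, type = "l", col = "firebrick",
                 xlab = "EDM cycle", ylab = "MPE (deg)",
                 ylim = c(0, 180), ...)
  graphics::abline(h = x$config$solved_mpe_threshold, lty = 3)
  graphics::par(new = TRUE)
  graphics::plot(tr$cycle, tr$rf, type = "l", col = "steelblue",
                 axes = FALSE, xlab = "", ylab = "", ylim = c(0, 1))
  graphics::axis(4)
  graphics::mtext("Rf", side = 4, line = 2.5, col = "steelblue")
  invisible(x)
}
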