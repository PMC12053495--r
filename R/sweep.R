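#' Pre-EDM MPE versus seed size
#'
#' The pre-processing curve: for each seed percentage, reflections are
#' seeded and phases assigned (no EDM), and the mean phase error against
#' the truth is averaged over independent seedings. The curve starts near
#' 90 degrees at Perc_seed = 0 and decreases linearly with seed size.
#'
#' @param refs A `reflection_set` with `phi_true` (and `e_value` for the
#'   `e_*` seed modes).
#' @param k Sampling density (2, 3, 4 or 6).
#' @param mode Seed-selection strategy, see [select_seed()].
#' @param perc_grid Ascending seed percentages in \[0, 100\].
#' @param n_repeats Independent seedings averaged per grid point.
#' @param e_threshold E-value floor for `e_random`.
#' @return Data frame with columns `perc_seed`, `mpe` (mean over repeats)
#'   and `mpe_sd`.
#' @export
mpe_vs_seed_curve <- function(refs, k, mode = "random",
                              perc_grid = seq(0, 100, 10), n_repeats = 10,
                              e_threshold = 1.0) {
  if (is.unsorted(perc_grid)) stop("perc_grid must be ascending")
  grid <- sampling_grid(k)
  res <- lapply(perc_grid, function(p) {
    m <- vapply(seq_len(n_repeats), function(i) {
      mask <- select_seed(refs, mode, perc_seed = p, e_threshold = e_threshold)
      pa <- assign_initial_phases(refs, mask, grid)
      mean_phase_error(pa, refs$phi_true)
    }, numeric(1))
    c(mean(m), stats::sd(m))
  })
  res <- do.call(rbind, res)
  data.frame(perc_seed = perc_grid, mpe = res[, 1], mpe_sd = res[, 2])
}

#' Find the minimum solving seed size (Perc_lim, MPE_lim)
#'
#' Walks the seed-percentage grid upward; at each value it runs
#' `n_repeats` independent seeding + EDM runs and applies the success
#' rule (default: at least half of the runs solved). Perc_lim is the
#' first grid value where the rule holds and MPE_lim is the mean pre-EDM
#' phase error of those runs. Both are `NA` when the structure is never
#' solved.
#'
#' @param refs A `reflection_set` with `f_obs` and `phi_true`.
#' @param k Sampling density.
#' @param mode Seed-selection strategy.
#' @param perc_grid Ascending seed percentages (default 10, 20, ..., 100).
#' @param n_repeats EDM runs per grid point (default 5).
#' @param config An [edm_config()].
#' @param success_rule Function `(n_solved, n_runs) -> logical`; default
#'   majority.
#' @param e_threshold E-value floor for `e_random`.
#' @return List of class `sweep_result` with `perc_lim`, `mpe_lim`, and
#'   `detail` (per-grid-point data frame: `perc_seed`, `n_runs`,
#'   `n_solved`, `mpe_pre`, `mpe_final`).
#' @export
find_perc_lim <- function(refs, k, mode = "random",
                          perc_grid = seq(10, 100, 10), n_repeats = 5,
                          config = edm_config(), success_rule = NULL,
                          e_threshold = 1.0) {
  if (is.unsorted(perc_grid)) stop("perc_grid must be ascending")
  if (is.null(success_rule))
    success_rule <- function(n_solved, n_runs) n_solved >= ceiling(n_runs / 2)
  grid <- sampling_grid(k)
  detail <- data.frame()
  perc_lim <- NA_real_; mpe_lim <- NA_real_
  for (p in perc_grid) {
    solved <- logical(n_repeats)
    mpe_pre <- mpe_fin <- numeric(n_repeats)
    for (i in seq_len(n_repeats)) {
      mask <- select_seed(refs, mode, perc_seed = p, e_threshold = e_threshold)
      pa <- assign_initial_phases(refs, mask, grid)
      run <- run_edm(refs, pa, config)
      solved[i] <- run$solved
      mpe_pre[i] <- run$mpe_initial
      mpe_fin[i] <- run$mpe_final
    }
    detail <- rbind(detail, data.frame(
      perc_seed = p, n_runs = n_repeats, n_solved = sum(solved),
      mpe_pre = mean(mpe_pre), mpe_final = mean(mpe_fin)))
    if (success_rule(sum(solved), n_repeats)) {
      perc_lim <- p
      mpe_lim <- mean(mpe_pre)
      break
    }
  }
  structure(list(perc_lim = perc_lim, mpe_lim = mpe_lim, detail = detail,
                 k = k, mode = mode),
            class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf("Seed-size sweep (k = %d, mode = %s): ", x$k, x$mode))
  if (is.na(x$perc_lim)) cat("never solved on the tested grid\n")
  else cat(sprintf("Perc_lim = %g%%, MPE_lim = %.1f deg\n",
                   x$perc_lim, x$mpe_lim))
  print(x$detail, row.names = FALSE)
  invisible(x)
}

#' Sweep a cohort of structures
#'
#' Runs [find_perc_lim()] for every combination of structure, sampling
#' density and seed mode, returning one row per combination.
#'
#' @param cohort List of lists with elements `structure` and `refs` (as
#'   returned by [synthetic_preset()]), optionally named.
#' @param ks Sampling densities to test.
#' @param modes Seed modes to test.
#' @param size_class Optional character vector of size-class labels, one
#'   per cohort entry (defaults to all `"small"`).
#' @param ... Passed to [find_perc_lim()].
#' @return Data frame with columns `structure`, `size_class`, `k`, `mode`,
#'   `perc_lim`, `mpe_lim`, `solved`.
#' @export
sweep_cohort <- function(cohort, ks = c(3, 4), modes = c("random", "e_random"),
                         size_class = NULL, ...) {
  if (length(cohort) < 1) stop("empty cohort")
  ids <- names(cohort)
  if (is.null(ids)) ids <- sprintf("structure_%02d", seq_along(cohort))
  if (is.null(size_class)) size_class <- rep("small", length(cohort))
  out <- data.frame()
  for (i in seq_along(cohort)) {
    for (k in ks) for (mode in modes) {
      sr <- find_perc_lim(cohort[[i]]$refs, k, mode, ...)
      out <- rbind(out, data.frame(
        structure = ids[i], size_class = size_class[i], k = k, mode = mode,
        perc_lim = sr$perc_lim, mpe_lim = sr$mpe_lim,
        solved = !is.na(sr$perc_lim)))
    }
  }
  out
}

#' Aggregate sweep results
#'
#' Summarises Perc_lim and MPE_lim distributions per (size class, k,
#' mode): mean, median, quartiles and the count of unsolved structures
#' (excluded from the distribution but reported, never silently dropped).
#'
#' @param results Data frame from [sweep_cohort()] (or rbind of several).
#' @return Data frame with one row per (size_class, k, mode) group.
#' @export
aggregate_sweep <- function(results) {
  if (nrow(results) < 1) stop("no sweep results to aggregate")
  groups <- unique(results[, c("size_class", "k", "mode")])
  out <- data.frame()
  for (g in seq_len(nrow(groups))) {
    sel <- results$size_class == groups$size_class[g] &
      results$k == groups$k[g] & results$mode == groups$mode[g]
    r <- results[sel, ]
    pl <- r$perc_lim[!is.na(r$perc_lim)]
    ml <- r$mpe_lim[!is.na(r$mpe_lim)]
    q <- if (length(pl)) stats::quantile(pl, c(0.25, 0.5, 0.75))
         else rep(NA_real_, 3)
    out <- rbind(out, data.frame(
      size_class = groups$size_class[g], k = groups$k[g],
      mode = groups$mode[g], n = nrow(r), n_unsolved = sum(is.na(r$perc_lim)),
      perc_lim_mean = if (length(pl)) mean(pl) else NA_real_,
      perc_lim_q1 = q[[1]], perc_lim_median = q[[2]], perc_lim_q3 = q[[3]],
      mpe_lim_mean = if (length(ml)) mean(ml) else NA_real_))
  }
  out
}
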