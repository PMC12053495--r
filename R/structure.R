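#' Crystal structure
#'
#' A ground-truth atomic model: unit cell, space group and the atom sites
#' of the asymmetric unit (fractional coordinates). `n_asym` counts the
#' non-hydrogen sites and `z_max` is the largest atomic number present,
#' the two structure covariates used throughout the seeding study.
#'
#' @param cell A [unit_cell()].
#' @param sg A [spacegroup()].
#' @param sites Data frame with columns `element` (symbol), `x`, `y`, `z`
#'   (fractional, reduced mod 1 into \[0,1)), and optionally `occ`
#'   (occupancy in (0,1\], default 1) and `b_iso` (isotropic displacement
#'   in A^2, default 3, must be >= 0).
#' @param check_clash Minimum allowed distance in Angstrom between any two
#'   symmetry/lattice-expanded atoms, or `NULL` to skip the check.
#' @return Object of class `crystal_structure`.
#' @export
crystal_structure <- function(cell, sg, sites, check_clash = NULL) {
  stopifnot(inherits(cell, "unit_cell"), inherits(sg, "spacegroup"))
  sites <- as.data.frame(sites)
  need <- c("element", "x", "y", "z")
  if (!all(need %in% names(sites)))
    stop("sites must have columns element, x, y, z")
  if (is.null(sites$occ)) sites$occ <- 1
  if (is.null(sites$b_iso)) sites$b_iso <- 3
  if (nrow(sites) < 1) stop("need at least one atom site")
  if (any(sites$occ <= 0 | sites$occ > 1)) stop("occupancy must be in (0,1]")
  if (any(sites$b_iso < 0)) stop("b_iso must be non-negative")
  sites$x <- sites$x %% 1; sites$y <- sites$y %% 1; sites$z <- sites$z %% 1
  z <- atomic_number(sites$element)
  if (!is.null(check_clash)) {
    dmin <- min_interatomic_distance(cell, sg, sites)
    if (dmin < check_clash)
      stop(sprintf("atom clash: minimum interatomic distance %.3f A < %.3f A",
                   dmin, check_clash))
  }
  structure(
    list(cell = cell, spacegroup = sg, sites = sites,
         n_asym = sum(z > 1), z_max = max(z)),
    class = "crystal_structure"
  )
}

#' @export
print.crystal_structure <- function(x, ...) {
  cat(sprintf("Crystal structure: %d sites in the asymmetric unit (N_asym = %d non-H, Z_max = %d), %s\n",
              nrow(x$sites), x$n_asym, x$z_max, x$spacegroup$symbol))
  print(x$cell)
  invisible(x)
}

# fractional coords of the full cell content (all symmetry copies)
expand_sites <- function(sg, xyz) {
  do.call(rbind, lapply(sg$ops, function(op) {
    (xyz %*% t(op$R) + rep(op$t, each = nrow(xyz))) %% 1
  }))
}

# minimum distance over all symmetry + periodic images (Angstrom)
min_interatomic_distance <- function(cell, sg, sites) {
  xyz <- as.matrix(sites[, c("x", "y", "z")])
  full <- expand_sites(sg, xyz)
  n <- nrow(full)
  if (n < 2 && sg$n_ops == 1) return(Inf)
  shifts <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  best <- Inf
  for (i in seq_len(n)) {
    dv <- full[rep(i, n), , drop = FALSE] - full
    for (s in seq_len(nrow(shifts))) {
      dd <- dv + rep(shifts[s, ], each = n)
      r2 <- rowSums((dd %*% cell$G) * dd)
      r2[i] <- if (all(shifts[s, ] == 0)) Inf else r2[i]
      best <- min(best, min(r2))
    }
  }
  sqrt(best)
}

#' Structure factors from an atomic model
#'
#' Computes true amplitudes and phases for every reflection in the set by
#' the direct summation F(h) = sum_ops sum_atoms occ f_el(s) exp(-B s^2/4)
#' exp(+2 pi i h . (R x + t)), with s = sin(theta)/lambda = 1/(2d) and
#' Cromer-Mann form factors. Phases are reported in degrees in \[0, 360).
#'
#' @param structure A [crystal_structure()].
#' @param refs A `reflection_set` for the same cell/space group.
#' @return The reflection set with columns `f_true` and `phi_true` filled
#'   (and `f_obs` initialized to `f_true` if not already present).
#' @export
calc_structure_factors <- function(structure, refs) {
  stopifnot(inherits(structure, "crystal_structure"),
            inherits(refs, "reflection_set"))
  sites <- structure$sites
  H <- hkl_matrix(refs)
  n <- nrow(H)
  if (n == 0) {
    refs$f_true <- numeric(0); refs$phi_true <- numeric(0)
    return(refs)
  }
  stol <- 1 / (2 * refs$d)
  xyz <- as.matrix(sites[, c("x", "y", "z")])
  # per-element form-factor curves, n_refl x n_atoms, with occupancy and
  # Debye-Waller damping folded in
  W <- matrix(0, n, nrow(sites))
  for (el in unique(sites$element)) {
    j <- which(sites$element == el)
    W[, j] <- scattering_factor(el, stol)
  }
  W <- W * exp(-outer(stol^2, sites$b_iso)) *
    matrix(sites$occ, n, nrow(sites), byrow = TRUE)
  Fc <- complex(real = rep(0, n))
  for (op in structure$spacegroup$ops) {
    xs <- xyz %*% t(op$R) + rep(op$t, each = nrow(xyz))
    P <- H %*% t(xs)                       # h . (R x + t), n_refl x n_atoms
    Fc <- Fc + rowSums(W * exp(2i * pi * P))
  }
  refs$f_true <- Mod(Fc)
  refs$phi_true <- (Arg(Fc) * 180 / pi) %% 360
  if (is.null(refs$f_obs)) refs$f_obs <- refs$f_true
  refs
}
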