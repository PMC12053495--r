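#' Centric classification of a reflection
#'
#' A reflection h is centric (phase-restricted) in a non-centrosymmetric
#' group when some symmetry rotation maps h onto -h; its phase is then
#' restricted to two values 180 degrees apart, phi0 and phi0 + 180, with
#' phi0 = 180 * (h . t) mod 180 for the translation t of that operator.
#' epsilon is the statistical weight of the reflection: the number of
#' rotations that leave h fixed.
#'
#' Reflections transform under the row-vector convention h' = h R, where R
#' acts on fractional coordinates as x' = R x + t.
#'
#' @param sg A [spacegroup()].
#' @param hkl Length-3 integer vector (not (0,0,0)).
#' @return List with `centric` (logical), `allowed_phases` (two degrees in
#'   [0,360), or `NULL` for general reflections), `epsilon` (integer), and
#'   `absent` (logical: `TRUE` for a systematic absence, where symmetry
#'   forces F = 0).
#' @examples
#' classify_reflection(spacegroup("P21"), c(1, 0, 2))
#' @export
classify_reflection <- function(sg, hkl) {
  h <- as.integer(hkl)
  if (length(h) != 3L || all(h == 0L))
    stop("invalid reflection: need non-zero integer (h,k,l)")
  centric <- FALSE
  phi0 <- NULL
  epsilon <- 0L
  absent <- FALSE
  for (op in sg$ops) {
    hr <- as.integer(round(h %*% op$R))
    if (all(hr == h)) {
      epsilon <- epsilon + 1L
      ht <- sum(h * op$t)
      if (abs(ht - round(ht)) > 1e-9) absent <- TRUE
    }
    if (all(hr == -h) && !centric) {
      centric <- TRUE
      phi0 <- (180 * sum(h * op$t)) %% 180
    }
  }
  allowed <- if (centric) c(phi0, phi0 + 180) %% 360 else NULL
  list(centric = centric, allowed_phases = allowed,
       epsilon = epsilon, absent = absent)
}

#' Generate the symmetry-unique reflection set
#'
#' Enumerates all reciprocal-lattice points with d >= `d_min`, merges
#' symmetry equivalents and Friedel mates, drops F(000) and systematic
#' absences, and returns one representative per orbit (the lexicographically
#' largest (h,k,l) member), each carrying its resolution, centric flag,
#' allowed restricted phases, epsilon weight and orbit multiplicity.
#'
#' @param cell A [unit_cell()].
#' @param sg A [spacegroup()].
#' @param d_min Resolution cutoff in Angstrom (> 0).
#' @param wavelength Radiation wavelength in Angstrom, stored as metadata
#'   (default 1.54056, Cu K-alpha).
#' @return A `reflection_set`: a data frame with columns `h`, `k`, `l`,
#'   `d`, `centric`, `phi_restrict` (phi0 in degrees, `NA` for general
#'   reflections), `epsilon`, `mult`, plus attributes `cell`, `spacegroup`,
#'   `d_min` and `wavelength`. Columns `f_true`, `phi_true`, `f_obs`,
#'   `e_value` are added by downstream operations.
#' @examples
#' refs <- unique_reflections(unit_cell(10, 10, 10), spacegroup("P1"), 5)
#' nrow(refs) # 16
#' @export
unique_reflections <- function(cell, sg, d_min, wavelength = 1.54056) {
  stopifnot(inherits(cell, "unit_cell"), inherits(sg, "spacegroup"))
  if (!is.finite(d_min) || d_min <= 0) stop("d_min must be positive")
  hmax <- floor(c(cell$a, cell$b, cell$c) / d_min)
  if (all(hmax == 0)) {
    warning("no reflections with d >= d_min = ", d_min, " A")
    return(empty_reflection_set(cell, sg, d_min, wavelength))
  }
  grid <- expand.grid(h = -hmax[1]:hmax[1], k = -hmax[2]:hmax[2],
                      l = -hmax[3]:hmax[3])
  H <- as.matrix(grid)
  storage.mode(H) <- "double"
  keep <- rowSums(H != 0) > 0
  H <- H[keep, , drop = FALSE]
  inv_d2 <- rowSums((H %*% cell$Gstar) * H)
  H <- H[inv_d2 <= 1 / d_min^2 + 1e-12, , drop = FALSE]
  if (nrow(H) == 0) {
    warning("no reflections with d >= d_min = ", d_min, " A")
    return(empty_reflection_set(cell, sg, d_min, wavelength))
  }
  # orbit representative: lexicographically largest member of
  # {h R_s} union {-h R_s}; encode (h,k,l) as a single comparable key
  base <- 2 * max(hmax) + 3
  enc <- function(M) (M[, 1] * base + M[, 2]) * base + M[, 3]
  rots <- sg_rotations(sg)
  n <- nrow(H)
  keymat <- matrix(0, n, 2 * length(rots))
  for (s in seq_along(rots)) {
    Hs <- H %*% rots[[s]]
    keymat[, 2 * s - 1] <- enc(Hs)
    keymat[, 2 * s] <- enc(-Hs)
  }
  self <- enc(H)
  is_rep <- self == apply(keymat, 1, max)
  mult <- apply(keymat, 1, function(r) length(unique(r)))
  H <- H[is_rep, , drop = FALSE]
  mult <- mult[is_rep]
  cls <- lapply(seq_len(nrow(H)), function(i) classify_reflection(sg, H[i, ]))
  absent <- vapply(cls, `[[`, logical(1), "absent")
  H <- H[!absent, , drop = FALSE]
  mult <- mult[!absent]
  cls <- cls[!absent]
  if (nrow(H) == 0) {
    warning("no reflections with d >= d_min = ", d_min, " A")
    return(empty_reflection_set(cell, sg, d_min, wavelength))
  }
  df <- data.frame(
    h = as.integer(H[, 1]), k = as.integer(H[, 2]), l = as.integer(H[, 3]),
    d = d_spacing(cell, H),
    centric = vapply(cls, `[[`, logical(1), "centric"),
    phi_restrict = vapply(cls, function(x)
      if (x$centric) x$allowed_phases[1] else NA_real_, numeric(1)),
    epsilon = vapply(cls, `[[`, integer(1), "epsilon"),
    mult = as.integer(mult)
  )
  df <- df[order(-df$d, df$h, df$k, df$l), ]
  rownames(df) <- NULL
  new_reflection_set(df, cell, sg, d_min, wavelength)
}

new_reflection_set <- function(df, cell, sg, d_min, wavelength) {
  structure(df, class = c("reflection_set", "data.frame"),
            cell = cell, spacegroup = sg, d_min = d_min,
            wavelength = wavelength)
}

empty_reflection_set <- function(cell, sg, d_min, wavelength) {
  df <- data.frame(h = integer(0), k = integer(0), l = integer(0),
                   d = numeric(0), centric = logical(0),
                   phi_restrict = numeric(0), epsilon = integer(0),
                   mult = integer(0))
  new_reflection_set(df, cell, sg, d_min, wavelength)
}

#' @export
print.reflection_set <- function(x, ...) {
  cat(sprintf(
    "Reflection set: %d symmetry-independent reflections, %s, d_min = %.3g A\n",
    nrow(x), attr(x, "spacegroup")$symbol, attr(x, "d_min")))
  if (nrow(x) > 0)
    cat(sprintf("  centric: %d (%.1f%%)%s\n", sum(x$centric),
                100 * mean(x$centric),
                if (!is.null(x$f_true)) "  [amplitudes computed]" else ""))
  invisible(x)
}

hkl_matrix <- function(refs) {
  H <- cbind(refs$h, refs$k, refs$l)
  storage.mode(H) <- "double"
  H
}

# subsetting keeps the class and metadata
#' @export
`[.reflection_set` <- function(x, i, j, ...) {
  out <- NextMethod()
  if (is.data.frame(out) && identical(names(out), names(x)))
    out <- new_reflection_set(as.data.frame(out), attr(x, "cell"),
                              attr(x, "spacegroup"), attr(x, "d_min"),
                              attr(x, "wavelength"))
  out
}
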