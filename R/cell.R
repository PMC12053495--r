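#' Unit cell
#'
#' Construct a crystallographic unit cell from its six lattice parameters.
#' The direct and reciprocal metric tensors and the cell volume are
#' precomputed and stored with the object.
#'
#' @param a,b,c Cell edge lengths in Angstrom. Must be positive.
#' @param alpha,beta,gamma Cell angles in degrees, each in (0, 180).
#'
#' @return An object of class `unit_cell`: a list with elements `a`, `b`,
#'   `c`, `alpha`, `beta`, `gamma`, the 3x3 direct metric tensor `G`, the
#'   reciprocal metric tensor `Gstar`, the orthogonalization matrix `orth`
#'   (fractional -> Cartesian, a along x) and the cell volume `volume` in
#'   cubic Angstrom.
#' @examples
#' cell <- unit_cell(10, 10, 10)
#' cell$volume
#' @export
unit_cell <- function(a, b, c, alpha = 90, beta = 90, gamma = 90) {
  len <- c(a, b, c)
  ang <- c(alpha, beta, gamma)
  if (any(!is.finite(len)) || any(len <= 0))
    stop("cell lengths must be positive and finite")
  if (any(!is.finite(ang)) || any(ang <= 0) || any(ang >= 180))
    stop("cell angles must lie in (0, 180) degrees")
  ca <- cos(ang * pi / 180)
  G <- matrix(c(
    a * a,           a * b * ca[3],  a * c * ca[2],
    a * b * ca[3],   b * b,          b * c * ca[1],
    a * c * ca[2],   b * c * ca[1],  c * c
  ), nrow = 3, byrow = TRUE)
  ev <- eigen(G, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev <= 0))
    stop("degenerate cell: metric tensor is not positive definite")
  vol <- sqrt(det(G))
  # standard PDB-style orthogonalization: a along x, b in the xy plane
  sg <- sin(gamma * pi / 180)
  cstar <- vol / (a * b * sg)
  orth <- matrix(c(
    a, b * ca[3], c * ca[2],
    0, b * sg,    c * (ca[1] - ca[2] * ca[3]) / sg,
    0, 0,         cstar
  ), nrow = 3, byrow = TRUE)
  structure(
    list(a = a, b = b, c = c, alpha = alpha, beta = beta, gamma = gamma,
         G = G, Gstar = solve(G), orth = orth, volume = vol),
    class = "unit_cell"
  )
}

#' @export
print.unit_cell <- function(x, ...) {
  cat(sprintf("Unit cell: a=%.4g b=%.4g c=%.4g A  alpha=%.4g beta=%.4g gamma=%.4g deg  V=%.4g A^3\n",
              x$a, x$b, x$c, x$alpha, x$beta, x$gamma, x$volume))
  invisible(x)
}

#' Resolution of a reflection
#'
#' d-spacing of one or more reflections, computed through the reciprocal
#' metric tensor: 1/d^2 = h G* h'. Consistent with Bragg's law
#' d = lambda / (2 sin theta) for any wavelength.
#'
#' @param cell A [unit_cell()].
#' @param hkl Integer vector of length 3, or an n x 3 matrix of Miller
#'   indices (one reflection per row). (0,0,0) is rejected.
#' @return Numeric vector of d-spacings in Angstrom.
#' @examples
#' d_spacing(unit_cell(10, 10, 10), c(1, 0, 0)) # 10
#' @export
d_spacing <- function(cell, hkl) {
  stopifnot(inherits(cell, "unit_cell"))
  H <- as_hkl_matrix(hkl)
  if (any(rowSums(H != 0L) == 0L))
    stop("invalid reflection (0,0,0): d-spacing undefined")
  inv_d2 <- rowSums((H %*% cell$Gstar) * H)
  1 / sqrt(inv_d2)
}

as_hkl_matrix <- function(hkl) {
  if (is.null(dim(hkl))) {
    if (length(hkl) != 3L) stop("hkl must have 3 components")
    hkl <- matrix(hkl, nrow = 1L)
  }
  H <- as.matrix(hkl)
  if (ncol(H) != 3L) stop("hkl matrix must have 3 columns")
  storage.mode(H) <- "double"
  if (any(H != round(H))) stop("Miller indices must be integers")
  H
}
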