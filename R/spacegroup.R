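#' Space groups
#'
#' Curated operator tables for a representative set of non-centrosymmetric
#' space groups: P1, P21, C2, P212121, P31 and R3 (hexagonal setting).
#' These cover identity-only symmetry, screw axes, lattice centring and the
#' trigonal groups that have no symmetry-restricted reflections. Operators
#' are stored as explicit rotation matrices and translation vectors, with
#' centring translations written out, so the list always generates the full
#' unit-cell content from the asymmetric unit.
#'
#' @param symbol Hermann-Mauguin symbol as a string (spaces and subscripts
#'   removed: "P21", "P212121", ...), or a character vector of xyz-triplet
#'   operator strings (e.g. `c("x,y,z", "-x,y+1/2,-z")`) to build a custom
#'   group.
#' @return An object of class `spacegroup`: list with `symbol`, `ops` (list
#'   of `list(R = 3x3 integer rotation, t = length-3 translation)`),
#'   `n_ops`, and `is_centrosymmetric` (always `FALSE` for the curated set;
#'   checked and rejected for custom operator lists).
#' @examples
#' sg <- spacegroup("P21")
#' sg$n_ops
#' @export
spacegroup <- function(symbol) {
  if (length(symbol) > 1L || grepl(",", symbol[1])) {
    ops <- lapply(symbol, parse_xyz_op)
    sym <- "custom"
  } else {
    tab <- spacegroup_table()
    key <- toupper(gsub("[ _]", "", symbol))
    if (!key %in% names(tab))
      stop("unknown space group '", symbol, "'; supported: ",
           paste(names(tab), collapse = ", "))
    ops <- lapply(tab[[key]], parse_xyz_op)
    sym <- key
  }
  sg <- validate_group(ops)
  structure(
    list(symbol = sym, ops = ops, n_ops = length(ops),
         is_centrosymmetric = sg$centro),
    class = "spacegroup"
  )
}

#' @export
print.spacegroup <- function(x, ...) {
  cat(sprintf("Space group %s (%d symmetry operators, non-centrosymmetric)\n",
              x$symbol, x$n_ops))
  invisible(x)
}

#' Supported space-group symbols
#'
#' @return Character vector of Hermann-Mauguin symbols accepted by
#'   [spacegroup()].
#' @export
supported_spacegroups <- function() names(spacegroup_table())

# Operator strings are shipped as a plain-text data file so the table can be
# inspected and extended without touching code.
spacegroup_table <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    path <- system.file("extdata", "spacegroups.txt", package = "phaseseed")
    if (path == "") path <- file.path("inst", "extdata", "spacegroups.txt")
    lines <- readLines(path)
    lines <- trimws(lines)
    lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
    tab <- list()
    cur <- NULL
    for (ln in lines) {
      if (startsWith(ln, "group ")) {
        cur <- toupper(strsplit(ln, "\\s+")[[1]][2])
        tab[[cur]] <- character(0)
      } else {
        tab[[cur]] <- c(tab[[cur]], ln)
      }
    }
    cache <<- tab
    tab
  }
})

# Parse one xyz-triplet operator string, e.g. "-x,y+1/2,-z", into a
# rotation matrix (acting on fractional column vectors) and translation.
parse_xyz_op <- function(s) {
  parts <- strsplit(gsub("\\s", "", tolower(s)), ",")[[1]]
  if (length(parts) != 3L) stop("bad xyz operator string: '", s, "'")
  R <- matrix(0L, 3, 3)
  t <- numeric(3)
  for (i in 1:3) {
    expr <- parts[i]
    # tokenize into signed terms
    toks <- regmatches(expr, gregexpr("[+-]?[^+-]+", expr))[[1]]
    for (tok in toks) {
      sign <- if (startsWith(tok, "-")) -1L else 1L
      body <- sub("^[+-]", "", tok)
      if (body %in% c("x", "y", "z")) {
        j <- match(body, c("x", "y", "z"))
        R[i, j] <- R[i, j] + sign
      } else if (grepl("^[0-9]+/[0-9]+$", body)) {
        nm <- as.numeric(strsplit(body, "/")[[1]])
        t[i] <- t[i] + sign * nm[1] / nm[2]
      } else if (grepl("^[0-9.]+$", body)) {
        t[i] <- t[i] + sign * as.numeric(body)
      } else {
        stop("cannot parse term '", tok, "' in operator '", s, "'")
      }
    }
  }
  t <- t %% 1
  if (abs(abs(det(R)) - 1) > 1e-9)
    stop("operator '", s, "' has |det| != 1")
  list(R = R, t = t)
}

# Closure/identity checks; detects centrosymmetry (rejected: the phase
# discretization machinery targets non-centrosymmetric groups only).
validate_group <- function(ops) {
  keys <- vapply(ops, op_key, character(1))
  if (anyDuplicated(keys)) stop("duplicate symmetry operators")
  idkey <- op_key(list(R = diag(3), t = numeric(3)))
  if (!idkey %in% keys) stop("identity operator missing")
  for (a in ops) for (b in ops) {
    comp <- list(R = a$R %*% b$R, t = (a$R %*% b$t + a$t) %% 1)
    if (!op_key(comp) %in% keys)
      stop("operator set not closed under composition")
  }
  centro <- any(vapply(ops, function(o) all(o$R == -diag(3)), logical(1)))
  if (centro)
    stop("centrosymmetric operator sets are not supported: ",
         "phase discretization targets non-centrosymmetric groups")
  list(centro = FALSE)
}

op_key <- function(op) {
  paste(c(as.integer(round(op$R)), round(op$t * 12) %% 12), collapse = ",")
}

# Rotation parts stacked for vectorized use: list of 3x3 matrices.
sg_rotations <- function(sg) lapply(sg$ops, `[[`, "R")
sg_translations <- function(sg) lapply(sg$ops, `[[`, "t")
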