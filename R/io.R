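#' Read a free-format reflection file
#'
#' Whitespace-delimited lines `h k l F [sigma] [phi]`; `#` starts a
#' comment. Duplicate (h,k,l) entries and non-numeric fields are rejected
#' with the offending line number.
#'
#' @param path File path.
#' @param cell,sg,d_min,wavelength Metadata attached to the returned set
#'   (optional; `d_min` defaults to the smallest d present when a cell is
#'   given).
#' @return A `reflection_set` with `f_obs` (and `phi_true` if a phase
#'   column is present). Centric classification is filled when a space
#'   group is supplied.
#' @export
read_reflections <- function(path, cell = NULL, sg = NULL, d_min = NULL,
                             wavelength = 1.54056) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  keep <- which(nzchar(trimws(lines)))
  if (length(keep) == 0) stop("no reflections in '", path, "'")
  rows <- lapply(keep, function(i) {
    toks <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(toks) < 4 || length(toks) > 6)
      stop("line ", i, ": expected 'h k l F [sigma] [phi]', got ",
           length(toks), " fields")
    v <- suppressWarnings(as.numeric(toks))
    if (any(is.na(v))) stop("line ", i, ": non-numeric field")
    if (any(v[1:3] != round(v[1:3]))) stop("line ", i, ": non-integer index")
    c(v, rep(NA_real_, 6 - length(v)))
  })
  m <- do.call(rbind, rows)
  key <- paste(m[, 1], m[, 2], m[, 3])
  if (anyDuplicated(key)) {
    bad <- keep[which(duplicated(key))[1]]
    stop("duplicate reflection (", key[duplicated(key)][1], ") at line ", bad)
  }
  df <- data.frame(h = as.integer(m[, 1]), k = as.integer(m[, 2]),
                   l = as.integer(m[, 3]))
  if (!is.null(cell)) df$d <- d_spacing(cell, as.matrix(df[, 1:3]))
  else df$d <- NA_real_
  if (!is.null(sg)) {
    cls <- lapply(seq_len(nrow(df)), function(i)
      classify_reflection(sg, c(df$h[i], df$k[i], df$l[i])))
    df$centric <- vapply(cls, `[[`, logical(1), "centric")
    df$phi_restrict <- vapply(cls, function(x)
      if (x$centric) x$allowed_phases[1] else NA_real_, numeric(1))
    df$epsilon <- vapply(cls, `[[`, integer(1), "epsilon")
  } else {
    df$centric <- FALSE; df$phi_restrict <- NA_real_; df$epsilon <- 1L
  }
  df$mult <- 1L
  df$f_obs <- m[, 4]
  if (!all(is.na(m[, 5]))) df$sigma <- m[, 5]
  if (!all(is.na(m[, 6]))) df$phi_true <- m[, 6] %% 360
  if (is.null(d_min)) d_min <- if (!is.null(cell)) min(df$d) else NA_real_
  new_reflection_set(df,
                     cell %||% unit_cell(1, 1, 1),
                     sg %||% spacegroup("P1"),
                     d_min, wavelength)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a reflection file
#'
#' Emits the same free-format dialect read by [read_reflections()]:
#' `h k l F [sigma] [phi]`, amplitudes to 6 significant figures.
#'
#' @param refs A `reflection_set`.
#' @param path Output path.
#' @param amplitudes Column to write as F (default `f_obs`).
#' @param phases Optional phase column name to append (e.g. `"phi_true"`),
#'   or `NULL`.
#' @export
write_reflections <- function(refs, path, amplitudes = "f_obs",
                              phases = NULL) {
  f <- refs[[amplitudes]]
  if (is.null(f)) stop("no column '", amplitudes, "' to write")
  lines <- sprintf("%4d %4d %4d %s", refs$h, refs$k, refs$l,
                   formatC(f, format = "g", digits = 6))
  if (!is.null(phases)) {
    p <- refs[[phases]]
    if (is.null(p)) stop("no column '", phases, "' to write")
    sig <- refs$sigma %||% rep(0, nrow(refs))
    lines <- sprintf("%s %s %s", lines,
                     formatC(sig, format = "g", digits = 6),
                     formatC(p, format = "g", digits = 6))
  }
  writeLines(c("# h k l F [sigma] [phi]", lines), path)
  invisible(path)
}

#' Write a minimal CIF file
#'
#' Cell parameters, symmetry operators (xyz loop) and fractional atom
#' sites, sufficient to round-trip structures written by this package.
#'
#' @param structure A [crystal_structure()].
#' @param path Output path.
#' @param data_name CIF data block name.
#' @export
write_cif <- function(structure, path, data_name = "phaseseed") {
  cell <- structure$cell; sg <- structure$spacegroup
  ops <- vapply(sg$ops, op_to_xyz, character(1))
  s <- structure$sites
  lines <- c(
    paste0("data_", data_name),
    sprintf("_cell_length_a    %.6f", cell$a),
    sprintf("_cell_length_b    %.6f", cell$b),
    sprintf("_cell_length_c    %.6f", cell$c),
    sprintf("_cell_angle_alpha %.6f", cell$alpha),
    sprintf("_cell_angle_beta  %.6f", cell$beta),
    sprintf("_cell_angle_gamma %.6f", cell$gamma),
    sprintf("_space_group_name_H-M_alt '%s'", sg$symbol),
    "loop_",
    "_space_group_symop_operation_xyz",
    sprintf("  '%s'", ops),
    "loop_",
    "_atom_site_label",
    "_atom_site_type_symbol",
    "_atom_site_fract_x",
    "_atom_site_fract_y",
    "_atom_site_fract_z",
    "_atom_site_occupancy",
    "_atom_site_B_iso_or_equiv",
    sprintf("  %s%d %s %.6f %.6f %.6f %.4f %.4f",
            s$element, seq_len(nrow(s)), s$element,
            s$x, s$y, s$z, s$occ, s$b_iso))
  writeLines(lines, path)
  invisible(path)
}

op_to_xyz <- function(op) {
  term <- function(i) {
    parts <- character(0)
    for (j in 1:3) {
      r <- op$R[i, j]
      if (r != 0) {
        v <- c("x", "y", "z")[j]
        parts <- c(parts, if (r == 1) paste0("+", v)
                          else if (r == -1) paste0("-", v)
                          else paste0(ifelse(r > 0, "+", "-"), abs(r), v))
      }
    }
    t <- op$t[i]
    if (abs(t) > 1e-9) {
      fr <- c(`0.5` = "1/2", `0.25` = "1/4", `0.75` = "3/4")
      tf <- fr[as.character(round(t, 6))]
      if (is.na(tf)) {
        thirds <- round(t * 3)
        sixths <- round(t * 6)
        tf <- if (abs(t - thirds / 3) < 1e-9) paste0(thirds, "/3")
              else if (abs(t - sixths / 6) < 1e-9) paste0(sixths, "/6")
              else formatC(t, format = "g")
      }
      parts <- c(parts, paste0("+", tf))
    }
    sub("^\\+", "", paste(parts, collapse = ""))
  }
  paste(vapply(1:3, term, character(1)), collapse = ",")
}

#' Read a minimal CIF file
#'
#' Understands cell parameters, a symmetry xyz loop (or a recognised
#' Hermann-Mauguin symbol) and a fractional atom-site loop. Anything more
#' exotic is rejected loudly rather than half-parsed.
#'
#' @param path File path.
#' @param drop_hydrogens Drop H sites (default `TRUE`, matching the non-H
#'   convention of the atom-count covariate N_asym).
#' @return A [crystal_structure()].
#' @export
read_cif <- function(path, drop_hydrogens = TRUE) {
  lines <- readLines(path)
  lines <- trimws(lines)
  val <- function(tag) {
    ln <- grep(paste0("^", tag, "\\b"), lines, value = TRUE)
    if (length(ln) == 0) return(NULL)
    as.numeric(strsplit(ln[1], "\\s+")[[1]][2])
  }
  a <- val("_cell_length_a"); b <- val("_cell_length_b")
  cc <- val("_cell_length_c")
  if (is.null(a) || is.null(b) || is.null(cc))
    stop("CIF '", path, "': missing cell parameters")
  cell <- unit_cell(a, b, cc,
                    val("_cell_angle_alpha") %||% 90,
                    val("_cell_angle_beta") %||% 90,
                    val("_cell_angle_gamma") %||% 90)
  # symmetry: xyz loop preferred, H-M symbol fallback
  sg <- NULL
  isym <- grep("_space_group_symop_operation_xyz|_symmetry_equiv_pos_as_xyz",
               lines)
  if (length(isym)) {
    ops <- character(0)
    i <- isym[1] + 1
    while (i <= length(lines) && !startsWith(lines[i], "_") &&
           !startsWith(lines[i], "loop_") && nzchar(lines[i])) {
      op <- gsub("^[0-9]+\\s+|'", "", lines[i])
      if (grepl(",", op)) ops <- c(ops, op)
      i <- i + 1
    }
    if (length(ops)) sg <- spacegroup(ops)
  }
  if (is.null(sg)) {
    hm <- grep("_space_group_name_H-M", lines, value = TRUE)
    if (length(hm)) {
      sym <- gsub(".*'(.*)'.*", "\\1", hm[1])
      sg <- spacegroup(sym)
    }
  }
  if (is.null(sg)) stop("CIF '", path, "': no usable symmetry information")
  # atom sites
  iloop <- grep("^loop_", lines)
  sites <- NULL
  for (il in iloop) {
    i <- il + 1
    tags <- character(0)
    while (i <= length(lines) && startsWith(lines[i], "_")) {
      tags <- c(tags, strsplit(lines[i], "\\s+")[[1]][1])
      i <- i + 1
    }
    if (!any(grepl("_atom_site_fract_x", tags))) next
    rows <- list()
    while (i <= length(lines) && nzchar(lines[i]) &&
           !startsWith(lines[i], "_") && !startsWith(lines[i], "loop_") &&
           !startsWith(lines[i], "data_")) {
      rows[[length(rows) + 1]] <- strsplit(lines[i], "\\s+")[[1]]
      i <- i + 1
    }
    if (!length(rows)) stop("CIF '", path, "': empty atom_site loop")
    m <- do.call(rbind, rows)
    col <- function(tag) match(tag, tags)
    el_col <- col("_atom_site_type_symbol")
    if (is.na(el_col)) el_col <- col("_atom_site_label")
    num <- function(tag, default = NULL) {
      j <- col(tag)
      if (is.na(j)) return(default)
      # strip esd parentheses like 0.1234(5)
      as.numeric(sub("\\(.*\\)", "", m[, j]))
    }
    sites <- data.frame(
      element = normalize_element(m[, el_col]),
      x = num("_atom_site_fract_x"), y = num("_atom_site_fract_y"),
      z = num("_atom_site_fract_z"),
      occ = num("_atom_site_occupancy", 1),
      b_iso = num("_atom_site_B_iso_or_equiv", 3))
    break
  }
  if (is.null(sites)) stop("CIF '", path, "': no atom_site loop found")
  if (drop_hydrogens) sites <- sites[sites$element != "H", ]
  crystal_structure(cell, sg, sites)
}

#' Read a PDB file (CRYST1 + ATOM/HETATM records)
#'
#' Orthogonal coordinates are fractionalized through the CRYST1 cell with
#' the standard orthogonalization convention (a along x, b in the xy
#' plane). The space group must be one of the supported symbols.
#'
#' @param path File path.
#' @param drop_hydrogens Drop H atoms (default `TRUE`).
#' @return A [crystal_structure()].
#' @export
read_pdb <- function(path, drop_hydrogens = TRUE) {
  lines <- readLines(path)
  cr <- grep("^CRYST1", lines, value = TRUE)
  if (length(cr) == 0) stop("PDB '", path, "': missing CRYST1 record")
  a <- as.numeric(substr(cr[1], 7, 15));  b <- as.numeric(substr(cr[1], 16, 24))
  cc <- as.numeric(substr(cr[1], 25, 33))
  al <- as.numeric(substr(cr[1], 34, 40)); be <- as.numeric(substr(cr[1], 41, 47))
  ga <- as.numeric(substr(cr[1], 48, 54))
  sgname <- trimws(substr(cr[1], 56, 66))
  cell <- unit_cell(a, b, cc, al, be, ga)
  sg <- spacegroup(gsub("\\s", "", sgname))
  at <- grep("^(ATOM  |HETATM)", lines, value = TRUE)
  if (length(at) == 0) stop("PDB '", path, "': no ATOM/HETATM records")
  xyz <- cbind(as.numeric(substr(at, 31, 38)),
               as.numeric(substr(at, 39, 46)),
               as.numeric(substr(at, 47, 54)))
  el <- trimws(substr(at, 77, 78))
  noel <- !nzchar(el)
  if (any(noel)) el[noel] <- trimws(substr(at[noel], 13, 14))
  occ <- as.numeric(substr(at, 55, 60))
  bq <- as.numeric(substr(at, 61, 66))
  frac <- t(solve(cell$orth, t(xyz)))
  sites <- data.frame(element = normalize_element(el),
                      x = frac[, 1], y = frac[, 2], z = frac[, 3],
                      occ = ifelse(is.na(occ) | occ <= 0, 1, occ),
                      b_iso = ifelse(is.na(bq) | bq < 0, 20, bq))
  if (drop_hydrogens) sites <- sites[sites$element != "H", ]
  crystal_structure(cell, sg, sites)
}

#' Dump a phase assignment for audit
#'
#' Text table `h k l phi seed_flag`, one reflection per line.
#'
#' @param refs A `reflection_set`.
#' @param assignment A `phase_assignment` for the same reflections.
#' @param path Output path.
#' @export
write_phase_assignment <- function(refs, assignment, path) {
  lines <- sprintf("%4d %4d %4d %10.4f %d", refs$h, refs$k, refs$l,
                   assignment$phi_d, as.integer(assignment$seed))
  writeLines(c("# h k l phi seed_flag", lines), path)
  invisible(path)
}

#' Read / write a run configuration
#'
#' A YAML file with nested sections (`synth`, `seed`, `edm`, `sweep`) plus
#' the global `rng_seed` and `out_dir`. Loading fills in every default
#' explicitly, so a written configuration round-trips losslessly and a
#' run manifest is self-contained.
#'
#' @param path File path.
#' @return A list of class `run_config` with all defaults filled.
#' @export
read_run_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the yaml package is required for configuration files")
  raw <- yaml::read_yaml(path)
  cfg <- default_run_config()
  for (sec in names(cfg)) {
    if (is.list(cfg[[sec]]) && !is.null(raw[[sec]])) {
      bad <- setdiff(names(raw[[sec]]), names(cfg[[sec]]))
      if (length(bad))
        stop("unknown key(s) in [", sec, "]: ", paste(bad, collapse = ", "))
      cfg[[sec]][names(raw[[sec]])] <- raw[[sec]]
    } else if (!is.null(raw[[sec]])) {
      cfg[[sec]] <- raw[[sec]]
    }
  }
  bad <- setdiff(names(raw), names(cfg))
  if (length(bad))
    stop("unknown section(s): ", paste(bad, collapse = ", "))
  structure(cfg, class = "run_config")
}

#' @rdname read_run_config
#' @param cfg A `run_config` (or a list in the same shape).
#' @export
write_run_config <- function(cfg, path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the yaml package is required for configuration files")
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

default_run_config <- function() {
  list(
    rng_seed = 1L,
    out_dir = "phaseseed_out",
    synth = list(preset = "small", n_asym = 20L, spacegroup = "P21",
                 d_min = 0.85, target_density = 55, min_dist = 1.5,
                 noise_sigma = 0, heavy_atom = NULL, fwhm_2theta = 0),
    seed = list(mode = "random", perc_seed = 20, grid_k = 4L,
                h_max = NULL, e_threshold = 1.0),
    edm = list(n_cycles = 200L, keep_fraction = 0.03, free_lunch = TRUE,
               extension_factor = 0.8, solved_mpe_threshold = 45,
               grid_oversampling = 3, converge_tol = 0.05),
    sweep = list(perc_grid = seq(10, 100, 10), ks = c(3L, 4L),
                 modes = c("random", "e_random"), n_repeats = 5L)
  )
}
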