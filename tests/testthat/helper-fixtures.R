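# Shared fixtures, built once per test run. All randomness is seeded so
# expectations frozen against independent oracles stay valid.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, builder(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# 10-atom triclinic structure at 0.9 A: the small phase-recovery fixture
fx_p1_small <- function() fixture("p1_small", function() {
  set.seed(101)
  st <- generate_structure(10, "P1")
  list(st = st, refs = simulate_observations(st, 0.9))
})

# 20-atom monoclinic structure at 0.85 A: has ~13% centric reflections
fx_p21_small <- function() fixture("p21_small", function() {
  set.seed(202)
  st <- generate_structure(20, "P21")
  list(st = st, refs = simulate_observations(st, 0.85))
})

# tiny orthorhombic structure with a coarse data cutoff: cheap EDM grids
fx_tiny <- function() fixture("tiny", function() {
  set.seed(303)
  st <- generate_structure(6, "P212121", target_density = 40)
  list(st = st, refs = simulate_observations(st, 1.3))
})

# independent brute-force orbit oracle for reflection classification
oracle_classify <- function(sg, h) {
  orbit <- lapply(sg$ops, function(op) as.integer(round(h %*% op$R)))
  centric <- any(vapply(orbit, function(g) all(g == -h), logical(1)))
  eps <- sum(vapply(orbit, function(g) all(g == h), logical(1)))
  phi0 <- NULL
  if (centric) {
    cand <- vapply(sg$ops[vapply(orbit, function(g) all(g == -h), logical(1))],
                   function(op) (180 * sum(h * op$t)) %% 180, numeric(1))
    phi0 <- unique(round(cand, 6))
  }
  list(centric = centric, epsilon = eps, phi0 = phi0)
}

# independent direct-summation structure factor (no symmetry expansion
# shortcuts; loops over explicit full-cell sites)
oracle_structure_factor <- function(st, hkl) {
  xyz <- as.matrix(st$sites[, c("x", "y", "z")])
  d <- d_spacing(st$cell, hkl)
  stol <- 1 / (2 * d)
  total <- 0 + 0i
  for (op in st$spacegroup$ops) {
    for (j in seq_len(nrow(xyz))) {
      x <- (op$R %*% xyz[j, ] + op$t)
      f <- phaseseed:::scattering_factor(st$sites$element[j], stol) *
        exp(-st$sites$b_iso[j] * stol^2) * st$sites$occ[j]
      total <- total + f * exp(2i * pi * sum(hkl * x))
    }
  }
  total
}

circ_diff <- function(a, b) {
  d <- abs(a - b) %% 360
  pmin(d, 360 - d)
}
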