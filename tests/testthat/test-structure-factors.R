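make_p1_refs <- function(cell, d_min = 2) {
  unique_reflections(cell, spacegroup("P1"), d_min)
}

test_that("phase conventions follow the shift theorem", {
  cell <- unit_cell(8, 8, 8)
  refs <- make_p1_refs(cell)
  origin <- crystal_structure(cell, spacegroup("P1"),
                              data.frame(element = "C", x = 0, y = 0, z = 0))
  r1 <- calc_structure_factors(origin, refs)
  expect_true(all(circ_diff(r1$phi_true, 0) < 1e-8))
  shifted <- crystal_structure(cell, spacegroup("P1"),
                               data.frame(element = "C", x = 0.5, y = 0, z = 0))
  r2 <- calc_structure_factors(shifted, refs)
  h100 <- which(r2$h == 1 & r2$k == 0 & r2$l == 0)
  expect_equal(circ_diff(r2$phi_true[h100], 180), 0, tolerance = 1e-8)
  # a +/- pair is centrosymmetric: F real, phases 0 or 180
  pair <- crystal_structure(cell, spacegroup("P1"),
                            data.frame(element = "C",
                                       x = c(0.13, -0.13), y = c(0.27, -0.27),
                                       z = c(0.41, -0.41)))
  r3 <- calc_structure_factors(pair, refs)
  expect_true(all(pmin(circ_diff(r3$phi_true, 0),
                       circ_diff(r3$phi_true, 180)) < 1e-6))
})

test_that("structure factors match the direct-summation oracle", {
  fx <- fx_p21_small()
  refs <- fx$refs
  set.seed(7)
  for (i in sample(nrow(refs), 12)) {
    h <- c(refs$h[i], refs$k[i], refs$l[i])
    Fo <- oracle_structure_factor(fx$st, h)
    expect_equal(refs$f_true[i], Mod(Fo), tolerance = 1e-8)
    expect_equal(circ_diff(refs$phi_true[i], (Arg(Fo) * 180 / pi) %% 360), 0,
                 tolerance = 1e-6)
    # Friedel mate: equal amplitude, negated phase
    Fm <- oracle_structure_factor(fx$st, -h)
    expect_equal(Mod(Fm), Mod(Fo), tolerance = 1e-8)
    expect_equal(circ_diff((Arg(Fm) * 180 / pi) %% 360,
                           (-Arg(Fo) * 180 / pi) %% 360), 0, tolerance = 1e-6)
  }
})

test_that("centric reflections land on an allowed restricted phase", {
  refs <- fx_p21_small()$refs
  cen <- refs[refs$centric, ]
  expect_gt(nrow(cen), 20)
  err <- pmin(circ_diff(cen$phi_true, cen$phi_restrict),
              circ_diff(cen$phi_true, cen$phi_restrict + 180))
  expect_true(all(err < 1e-3))
})

test_that("amplitudes scale linearly with occupancy, phases unchanged", {
  fx <- fx_tiny()
  st2 <- fx$st
  st2$sites$occ <- 0.5
  refs <- unique_reflections(st2$cell, st2$spacegroup, 1.3)
  a <- calc_structure_factors(fx$st, refs)
  b <- calc_structure_factors(st2, refs)
  expect_equal(a$f_true, 2 * b$f_true, tolerance = 1e-10)
  expect_equal(circ_diff(a$phi_true, b$phi_true), rep(0, nrow(a)),
               tolerance = 1e-8)
})

test_that("E-normalization is resolution-flat with unit mean square", {
  refs <- fx_p21_small()$refs
  expect_equal(mean(refs$e_value^2), 1, tolerance = 0.02)
  s2 <- 1 / refs$d^2
  shell <- ceiling(rank(s2, ties.method = "first") * 10 / nrow(refs))
  for (sh in unique(shell))
    expect_equal(mean(refs$e_value[shell == sh]^2), 1, tolerance = 0.05)
  # acentric Wilson statistics: P(E > 1) = exp(-1)
  acen <- refs$e_value[!refs$centric]
  expect_equal(mean(acen > 1), exp(-1), tolerance = 0.08)
})

test_that("a one-atom structure has E near 1 everywhere", {
  cell <- unit_cell(7, 7, 7)
  st <- crystal_structure(cell, spacegroup("P1"),
                          data.frame(element = "C", x = 0.1, y = 0.2, z = 0.3,
                                     b_iso = 3))
  refs <- normalize_E(calc_structure_factors(st, make_p1_refs(cell, 1.5)))
  expect_true(all(abs(refs$e_value - 1) < 0.25))
  expect_lt(sd(refs$e_value), 0.1)
})

test_that("shell count shrinks with a warning on tiny sets", {
  cell <- unit_cell(6, 6, 6)
  st <- crystal_structure(cell, spacegroup("P1"),
                          data.frame(element = "C", x = 0.1, y = 0.2, z = 0.3))
  refs <- calc_structure_factors(st, make_p1_refs(cell, 3))
  expect_warning(normalize_E(refs, n_shells = 10), "reducing n_shells")
})

test_that("the R factor behaves as an agreement metric", {
  expect_equal(r_factor(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(r_factor(c(1, 2, 3), c(2, 4, 6)), 0)            # scale absorbed
  expect_gt(r_factor(c(1, 2, 3), c(2, 4, 6), scale = FALSE), 0)
  expect_error(r_factor(c(0, 0), c(1, 1)), "all zero")
  expect_error(r_factor(1:3, 1:4), "equal length")
  # amplitudes of two unrelated random structures: Rf settles in 0.5-0.6
  set.seed(99)
  rfs <- replicate(10, {
    s1 <- generate_structure(8, "P1")
    s2 <- generate_structure(8, "P1")
    r1 <- simulate_observations(s1, 1.1)
    r2 <- simulate_observations(s2, 1.1)
    n <- min(nrow(r1), nrow(r2))
    r_factor(r1$f_obs[seq_len(n)], r2$f_obs[seq_len(n)])
  })
  expect_gt(mean(rfs), 0.5)
  expect_lt(mean(rfs), 0.6)
})

test_that("unknown elements are reported by name", {
  cell <- unit_cell(8, 8, 8)
  expect_error(
    crystal_structure(cell, spacegroup("P1"),
                      data.frame(element = "Xx", x = 0, y = 0, z = 0)),
    "Xx")
})
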