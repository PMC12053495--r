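test_that("d-spacing follows the reciprocal metric tensor", {
  cubic <- unit_cell(10, 10, 10)
  expect_equal(d_spacing(cubic, c(1, 0, 0)), 10)
  expect_error(d_spacing(cubic, c(0, 0, 0)), "invalid reflection")
  # orthorhombic oracle: 1/d^2 = h^2/a^2 + k^2/b^2 + l^2/c^2
  ortho <- unit_cell(3, 4, 5)
  expect_equal(d_spacing(ortho, c(1, 1, 1)), 1 / sqrt(1/9 + 1/16 + 1/25),
               tolerance = 1e-10)
  # monoclinic consistency with the Cartesian orthogonalization matrix
  mono <- unit_cell(7, 5, 9, beta = 104)
  h <- c(2, -1, 3)
  astar <- solve(t(mono$orth))      # reciprocal basis vectors as columns
  expect_equal(d_spacing(mono, h), 1 / sqrt(sum((astar %*% h)^2)),
               tolerance = 1e-10)
})

test_that("unit cell validation rejects degenerate geometry", {
  expect_error(unit_cell(-1, 5, 5), "positive")
  expect_error(unit_cell(5, 5, 5, alpha = 190), "angles")
  # alpha + beta + gamma constraint violated -> metric not positive definite
  expect_error(unit_cell(5, 5, 5, 10, 10, 170), "positive definite")
})

test_that("centric classification matches brute-force orbit enumeration", {
  set.seed(42)
  for (sym in supported_spacegroups()) {
    sg <- spacegroup(sym)
    H <- matrix(sample(-6:6, 3 * 200, replace = TRUE), ncol = 3)
    H <- H[rowSums(H != 0) > 0, , drop = FALSE]
    for (i in seq_len(nrow(H))) {
      got <- classify_reflection(sg, H[i, ])
      want <- oracle_classify(sg, H[i, ])
      expect_identical(got$centric, want$centric)
      expect_identical(got$epsilon, want$epsilon)
      if (want$centric) {
        # the restricted phase is only well defined for non-absent
        # reflections; absences carry conflicting candidates and are
        # excluded from every reflection set
        if (!got$absent) expect_length(want$phi0, 1)
        expect_true((got$allowed_phases[1] %% 180) %in% (want$phi0 %% 180))
        expect_equal(circ_diff(got$allowed_phases[1], got$allowed_phases[2]),
                     180)
      } else {
        expect_null(got$allowed_phases)
      }
    }
  }
})

test_that("trigonal groups have no restricted reflections", {
  for (sym in c("P31", "R3")) {
    sg <- spacegroup(sym)
    H <- as.matrix(expand.grid(h = -3:3, k = -3:3, l = -3:3))
    H <- H[rowSums(H != 0) > 0, ]
    cen <- apply(H, 1, function(h) classify_reflection(sg, h)$centric)
    expect_false(any(cen))
  }
})

test_that("unique reflection generation counts and merges correctly", {
  cubic <- unit_cell(10, 10, 10)
  p1 <- unique_reflections(cubic, spacegroup("P1"), 5)
  expect_equal(nrow(p1), 16)  # lattice points with h^2+k^2+l^2 <= 4, Friedel-halved
  expect_true(all(p1$d >= 5 - 1e-9))
  expect_warning(unique_reflections(cubic, spacegroup("P1"), 11), "no reflections")
  # higher symmetry merges orbits: P21 unique set is a subset of P1's
  p21 <- unique_reflections(cubic, spacegroup("P21"), 5)
  key <- function(r) paste(r$h, r$k, r$l)
  expect_true(all(key(p21) %in% key(p1)))
  expect_lt(nrow(p21), nrow(p1))
})

test_that("orbit representatives cover the sphere exactly once", {
  for (sym in c("P21", "P212121")) {
    # cell metric must be compatible with the symmetry operators
    cell <- if (sym == "P21") unit_cell(8, 9, 11, beta = 104)
            else unit_cell(8, 9, 11)
    sg <- spacegroup(sym)
    refs <- unique_reflections(cell, sg, 2.0)
    # re-expand every representative through all ops and Friedel
    seen <- character(0)
    for (i in seq_len(nrow(refs))) {
      h <- c(refs$h[i], refs$k[i], refs$l[i])
      orb <- unique(do.call(rbind, lapply(sg$ops, function(op) {
        g <- as.integer(round(h %*% op$R)); rbind(g, -g)
      })))
      expect_equal(nrow(orb), refs$mult[i])
      seen <- c(seen, apply(orb, 1, paste, collapse = ","))
    }
    expect_false(any(duplicated(seen)))  # orbits are disjoint
    # and they exhaust all non-absent points with d >= d_min
    hmax <- floor(c(cell$a, cell$b, cell$c) / 2.0)
    all_h <- as.matrix(expand.grid(-hmax[1]:hmax[1], -hmax[2]:hmax[2],
                                   -hmax[3]:hmax[3]))
    all_h <- all_h[rowSums(all_h != 0) > 0, ]
    all_h <- all_h[d_spacing(cell, all_h) >= 2.0 - 1e-9, ]
    absent <- apply(all_h, 1, function(h) classify_reflection(sg, h)$absent)
    expect_setequal(seen, apply(all_h[!absent, ], 1, paste, collapse = ","))
  }
})

test_that("screw-axis systematic absences are excluded", {
  cell <- unit_cell(10, 10, 10)
  refs <- unique_reflections(cell, spacegroup("P21"), 2.5)
  axial <- refs[refs$h == 0 & refs$l == 0, ]
  expect_true(all(axial$k %% 2 == 0))  # (0,k,0) with odd k absent in P21
})

test_that("space group machinery validates operator sets", {
  expect_error(spacegroup("P63"), "unknown space group")
  expect_error(spacegroup(c("x,y,z", "-x,-y,-z")), "centrosymmetric")
  expect_error(spacegroup(c("x,y,z", "-y,x-y,z+1/3")), "not closed")
  custom <- spacegroup(c("x,y,z", "-x,y+1/2,-z"))
  expect_equal(custom$n_ops, 2)
})
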