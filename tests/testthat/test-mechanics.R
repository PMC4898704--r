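# Strand mechanics: WLC relations, element inversion, series equilibrium,
# force-curve family.

test_that("WLC force matches the interpolation formula and its limits", {
  pl <- 8.5e-10; cl <- 288e-9; Tk <- 300
  expect_identical(wlc_force(0, pl, cl, Tk), 0)
  expect_equal(wlc_force(cl / 2, pl, cl, Tk), 1.25 * kBT(Tk) / pl)
  # independent substitution at x = 0.9 cl
  x <- 0.9 * cl
  expected <- kBT(Tk) / pl * (0.25 * (1 - 0.9)^-2 - 0.25 + 0.9)
  expect_equal(wlc_force(x, pl, cl, Tk), expected)
  # strictly increasing, diverging toward cl
  xs <- seq(0, 0.999 * cl, length.out = 200)
  Fs <- wlc_force(xs, pl, cl, Tk)
  expect_true(all(diff(Fs) > 0))
  expect_gt(Fs[200], 1e4 * Fs[2])
  expect_error(wlc_force(cl, pl, cl, Tk), "contour")
  expect_error(wlc_force(-1e-9, pl, cl, Tk), ">= 0")
})

test_that("modified WLC satisfies its implicit relation and the WLC limit", {
  pl <- 6e-10; cl <- 288e-9; Tk <- 300
  expect_equal(modified_wlc_force(0, pl, cl, 150e-12, Tk), 0)
  # enthalpic compliance lowers the force below the pure WLC
  x <- 0.5 * cl
  Fm <- modified_wlc_force(x, pl, cl, 150e-12, Tk)
  expect_lt(Fm, wlc_force(x, pl, cl, Tk))
  # residual of the implicit relation is ~0
  y <- x / cl - Fm / 150e-12
  expect_equal(Fm, kBT(Tk) / pl * (0.25 * (1 - y)^-2 - 0.25 + y),
               tolerance = 1e-9)
  # F0 -> Inf recovers the WLC (relative deviation < 1e-5 at 1e4 x 150 pN)
  for (xx in c(0.2, 0.5, 0.8) * cl) {
    expect_equal(modified_wlc_force(xx, pl, cl, 1e4 * 150e-12, Tk),
                 wlc_force(xx, pl, cl, Tk), tolerance = 1e-5)
  }
  # extension beyond the contour length is admissible
  expect_gt(modified_wlc_force(1.2 * cl, pl, cl, 150e-12, Tk), 0)
})

test_that("element extension at force inverts each element kind", {
  expect_equal(element_length_at_force(spring_element(2), 2e-12), 1e-12)
  Tk <- 300
  els <- list(wlc_element(8.5e-10, 100e-9, Tk),
              mwlc_element(6e-10, 288e-9, 150e-12, Tk),
              spring_element(2))
  for (el in els) expect_equal(element_length_at_force(el, 0), 0)
  # round trip: force at the returned extension recovers F (rel tol 1e-9)
  Fgrid <- c(1e-13, 1e-12, 5e-12, 2e-11, 1e-10)
  x <- element_length_at_force(els[[1]], Fgrid)
  expect_equal(wlc_force(x, 8.5e-10, 100e-9, Tk), Fgrid, tolerance = 1e-9)
  x <- element_length_at_force(els[[2]], Fgrid)
  expect_equal(modified_wlc_force(x, 6e-10, 288e-9, 150e-12, Tk), Fgrid,
               tolerance = 1e-9)
  # strictly increasing in F
  expect_true(all(diff(element_length_at_force(els[[1]], Fgrid)) > 0))
})

test_that("solve_strand finds the series equilibrium", {
  p <- mechanical_params(); iso <- isoform()
  # below slack: zero force, slack absorbs the length
  s <- solve_strand(0.5 * p$slack_length, 0, p, iso)
  expect_identical(s$force, 0)
  expect_equal(sum(unlist(s$segments)), 0.5 * p$slack_length)
  # force decreases strictly with the number of unfolded domains
  Fs <- vapply(c(0, 10, 25, 40, 50),
               function(i) solve_strand(1.6e-6, i, p, iso)$force, numeric(1))
  expect_true(all(diff(Fs) < 0))
  # residuals: segments sum to l; every element carries the common force
  s <- solve_strand(1.55e-6, 20, p, iso)
  expect_equal(sum(unlist(s$segments)), 1.55e-6, tolerance = 1e-12)
  Tk <- p$temperature
  F <- s$force
  expect_equal(modified_wlc_force(s$segments$l_pevk, p$pl_pevk,
                                  iso$n_pevk_residues * p$cl_pevk_per_residue,
                                  p$F0, Tk), F, tolerance = 1e-9)
  expect_equal(wlc_force(s$segments$l_folded_total, p$pl_ig,
                         30 * p$cl_ig_per_unit, Tk), F, tolerance = 1e-9)
  expect_equal(wlc_force(s$segments$l_unfolded_total, p$pl_ig,
                         20 * p$d_u, Tk), F, tolerance = 1e-9)
  expect_equal(s$segments$l_end * p$k_end, F, tolerance = 1e-12)
  expect_equal((s$segments$l_rest - p$slack_length) * p$k_rest, F,
               tolerance = 1e-9)
  expect_error(solve_strand(1.5e-6, 51, p, iso), "n_unfolded")
})

test_that("force-curve family has N + 1 ordered curves with exact nodes", {
  mod <- toy_model()
  fam <- mod$curves
  expect_equal(nrow(fam$forces), 6)   # 5 domains -> 6 states
  # dominance and monotonicity over the whole family
  expect_true(all(fam$forces >= 0))
  for (j in seq_along(fam$length_grid))
    expect_true(all(diff(fam$forces[, j]) <= 1e-18))
  for (i in seq_len(nrow(fam$forces)))
    expect_true(all(diff(fam$forces[i, ]) >= -1e-18))
  # interpolation is exact at grid nodes
  expect_identical(force_at(fam, 2, fam$length_grid[35]),
                   fam$forces[3, 35])
  expect_error(build_force_curves(seq(1.5e-6, 2e-6, 1e-9)), "1 um")
  # CSV export round-trips values in interface units
  f <- tempfile(fileext = ".csv")
  write_force_curves_csv(fam, f)
  df <- read.csv(f)
  expect_equal(ncol(df), 7)
  expect_equal(df$F_0, fam$forces[1, ] * 1e12, tolerance = 1e-6)
})

test_that("full-scale family has 51 curves dominated by the all-folded one", {
  fam <- full_model()$curves
  expect_identical(nrow(fam$forces), 51L)
  top <- matrix(fam$forces[1, ], nrow = 50, ncol = ncol(fam$forces),
                byrow = TRUE)
  expect_true(all(top - fam$forces[-1, , drop = FALSE] >= -1e-18))
})
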