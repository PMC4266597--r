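test_that("FRC extension ratio approaches 1 at high force and increases", {
  pp <- polymer_params()
  expect_gte(frc_extension_ratio(1e5, pp), 0.99)
  expect_lt(frc_extension_ratio(200, pp), frc_extension_ratio(400, pp))
  grid <- seq(10, 2000, by = 5)
  r <- frc_extension_ratio(grid, pp)
  expect_true(all(diff(r) > 0))
  expect_true(all(r > 0 & r < 1))
})

test_that("FRC ratio matches an independent evaluation in both regimes", {
  pp <- polymer_params(qm_correction = NULL)
  # discrete-bond regime (above the ~124 pN crossover): closed form
  expect_equal(frc_extension_ratio(200, pp), 1 - 4.114 / (2 * 200 * 0.11),
               tolerance = 1e-12)
  expect_equal(frc_extension_ratio(200, pp), 0.9065, tolerance = 1e-9)
  # regression pin for the same point
  for (f in c(20, 60, 120, 124, 125, 200, 600, 1500)) {
    expect_equal(frc_extension_ratio(f, pp), oracle_frc_ratio(f),
                 tolerance = 1e-8, label = sprintf("ratio at %g pN", f))
  }
})

test_that("forces outside the validity range are flagged or rejected", {
  pp <- polymer_params()
  expect_error(frc_extension_ratio(-5, pp), "force")
  expect_error(frc_extension_ratio(0, pp), "force")
  expect_warning(frc_extension_ratio(5, pp), "validity floor")
})

test_that("backbone stretch factor is 1 at zero force and non-decreasing", {
  pp <- polymer_params()
  expect_identical(backbone_stretch_factor(0, pp), 1)
  expect_gte(backbone_stretch_factor(100, pp), 1)
  expect_gte(backbone_stretch_factor(600, pp),
             backbone_stretch_factor(100, pp))
  expect_error(backbone_stretch_factor(-1, pp), "force")
  # quadratic parametrization, independent polynomial evaluation
  cf <- pp$qm_correction
  expect_equal(backbone_stretch_factor(600, pp),
               1 + cf[1] * 600 + cf[2] * 600^2, tolerance = 1e-12)
  # disabling the correction reproduces the uncorrected chain exactly
  off <- polymer_params(qm_correction = NULL)
  expect_identical(backbone_stretch_factor(c(0, 250, 900), off),
                   rep(1, 3))
  expect_equal(forcespec:::extension_ratio(300, off),
               frc_extension_ratio(300, off), tolerance = 1e-12)
})

test_that("force_at_extension inverts the extension model", {
  pp <- polymer_params()
  L <- 120
  expect_identical(force_at_extension(0, L, pp), 0)
  for (f in c(30, 250, 900)) {
    x <- forcespec:::model_extension(f, L, pp)
    expect_equal(force_at_extension(x, L, pp), f, tolerance = 1e-6)
  }
  # WLC interpolation formula at half extension, independent closed form
  wp <- polymer_params("WLC", persistence_length = 0.38)
  f_oracle <- (4.114 / 0.38) * (1 / (4 * (1 - 0.5)^2) - 0.25 + 0.5)
  expect_equal(force_at_extension(0.5 * 80, 80, wp), f_oracle,
               tolerance = 1e-9)
  expect_error(force_at_extension(81, 80, wp), "exceeds")
  expect_error(force_at_extension(5000, 100, pp), "not attainable")
})

test_that("apparent contour length inverts the generator and rejects below threshold", {
  pp <- polymer_params()
  x <- forcespec:::model_extension(300, 100, pp)
  expect_equal(as.numeric(apparent_contour_length(300, x, pp)), 100,
               tolerance = 1e-6)
  out <- apparent_contour_length(c(5, 300), c(10, x), pp)
  expect_true(is.na(out[1]))
  expect_equal(attr(out, "n_rejected"), 1)
  # scale equivariance: doubling extension and true length doubles output
  expect_equal(as.numeric(apparent_contour_length(300, 2 * x, pp)), 200,
               tolerance = 1e-6)
  # Monte Carlo: noisy forces still recover the true contour length
  set.seed(99)
  f_true <- runif(2000, 150, 600)
  x_true <- forcespec:::model_extension(f_true, 150, pp)
  f_noisy <- f_true + rnorm(2000, 0, 5)
  l <- apparent_contour_length(f_noisy, x_true, pp)
  expect_lt(abs(mean(l, na.rm = TRUE) - 150), 1)
})

test_that("expected increments follow the stretched-residue arithmetic", {
  expect_equal(expected_increment(100, 5), 31.5)
  expect_equal(expected_increment(1, 0), 0.365)
  expect_error(expected_increment(10, 4.0), "exceeds")
  tab <- increment_table()
  expect_equal(tab$entries$increment,
               tab$entries$residues * 0.365 - tab$entries$folded_length)
  expect_true(all(tab$entries$increment > 0))
  # the shipped table reproduces the canonical fingerprints
  expect_equal(tab$entries$increment[tab$entries$name == "Xyn"], 89,
               tolerance = 0.01)
  expect_equal(tab$entries$increment[tab$entries$name == "CBM"], 56,
               tolerance = 0.01)
})
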