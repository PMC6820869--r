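test_that("knee-based seeding brackets the true radii", {
  m <- gox_reference_model(1)
  p <- simulate_unified(m, noise = noise_spec(fraction = 0))
  init <- unified_init(p, levels = 3)
  rg <- coef(init)[c("Rg1", "Rg2", "Rg3")]
  truth <- c(25.5, 110, 590)
  expect_true(all(rg / truth < 2 & rg / truth > 0.5))
})

test_that("single-level seeding gets a sphere's Rg within 10%", {
  p <- simulate_bead_target("sphere", R = 30, q = default_q_grid(300))
  init <- unified_init(p, levels = 1)
  expect_equal(coef(init)[["Rg1"]], sqrt(3 / 5) * 30, tolerance = 0.1)
})

test_that("a featureless curve falls back to a log-spaced ladder", {
  q <- default_q_grid(60)
  p <- scattering_profile(q, rep(2, 60), rep(0.01, 60))
  expect_warning(init <- unified_init(p, levels = 3), "ladder")
  rg <- coef(init)[c("Rg1", "Rg2", "Rg3")]
  expect_true(all(diff(rg) > 0))
})

test_that("noise-free fits return the generating parameters to 0.1%", {
  m <- gox_reference_model(1)
  p <- simulate_unified(m, noise = noise_spec(fraction = 0, floor = 1e-4))
  f <- unified_fit(p, levels = 3, seed = 1)
  expect_true(f$converged)
  rel <- abs(coef(f) / coef(m) - 1)[f$free]
  expect_lt(max(rel), 1e-3)
  # residuals of the noise-free round trip vanish
  expect_lt(max(abs(residuals(f, type = "raw"))), 1e-8 * max(p$I))
})

test_that("round-trip identity holds for other level counts", {
  # 2-level stack with well-separated radii (ratio >= 4)
  m <- unified_model(G = c(0.05, 12), Rg = c(30, 200), B = c(0, 1e-7),
                     df = c(4, 4))
  p <- simulate_unified(m, noise = noise_spec(fraction = 0, floor = 1e-5))
  f <- unified_fit(p, levels = 2, fixed = c(B1 = 0, df2 = 4), seed = 2)
  expect_lt(max(abs(coef(f) / coef(m) - 1)[f$free]), 1e-3)
  # single level
  m1 <- unified_model(G = 3, Rg = 45, B = 1e-5, df = 3.6)
  p1 <- simulate_unified(m1, noise = noise_spec(fraction = 0, floor = 1e-6))
  f1 <- unified_fit(p1, levels = 1, fixed = numeric(0), seed = 2)
  expect_lt(max(abs(coef(f1) / coef(m1) - 1)[f1$free]), 1e-3)
})

test_that("degenerate inputs are rejected", {
  p1 <- scattering_profile(0.01, 5, 0.1)
  expect_error(unified_fit(p1, levels = 3), "point")
})

test_that("calibration invariance: intensity rescaling moves only G and B", {
  rf <- ref_noisy_fit()
  p <- rf$profile
  c0 <- 7.5
  ps <- scattering_profile(p$q, c0 * p$I, c0 * p$sigma)
  f0 <- rf$fit
  fs <- suppressWarnings(unified_fit(ps, levels = 3, seed = 3))
  cf0 <- coef(f0); cfs <- coef(fs)
  amp <- c("G1", "G2", "G3", "B2", "B3")
  expect_equal(cfs[amp] / cf0[amp], setNames(rep(c0, 5), amp),
               tolerance = 1e-4)
  geom <- c("Rg1", "Rg2", "Rg3", "df2")
  expect_equal(cfs[geom], cf0[geom], tolerance = 1e-4)
})

test_that("the fit report decomposes the model additively", {
  rf <- ref_noisy_fit()
  rep <- fit_report(rf$fit)
  lv <- as.matrix(rep$curves[, c("level1", "level2", "level3")])
  expect_equal(rowSums(lv), rep$curves$total, tolerance = 1e-14)
  expect_equal(rep$residuals$weighted_residual,
               (rf$profile$I - fitted(rf$fit)) / rf$profile$sigma)
  # 2 % noise fits land at a sane goodness of fit
  expect_gt(rf$fit$chi2_reduced, 0.3)
  expect_lt(rf$fit$chi2_reduced, 2)
})

test_that("reported uncertainties are roughly calibrated (68% coverage)", {
  rep <- replicate_fits()
  z <- sapply(rep$fits, function(f)
    (coef(f)[rep$free] - rep$truth[rep$free]) / f$stderr[rep$free])
  cover <- mean(abs(z) <= 1, na.rm = TRUE)
  expect_gt(cover, 0.53)
  expect_lt(cover, 0.83)
})

test_that("aggregation numbers from noisy fits centre on the truth", {
  rep <- replicate_fits()
  za <- sapply(rep$fits, function(f) coef(f)[["G2"]] / coef(f)[["G1"]])
  # z_a ~ 10 +/- 2; guard the median against rare merged-level solutions
  expect_equal(median(za), 10, tolerance = 0.2)
})

test_that("simulate() draws replicates on the data grid", {
  rf <- ref_noisy_fit()
  s1 <- simulate(rf$fit, seed = 42)
  s2 <- simulate(rf$fit, seed = 42)
  expect_identical(s1$I, s2$I)
  expect_identical(s1$q, rf$profile$q)
  expect_false(identical(simulate(rf$fit, seed = 1)$I, s1$I))
})
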