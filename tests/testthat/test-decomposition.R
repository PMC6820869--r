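test_that("level curves sum to the experimental intensity exactly", {
  rf <- ref_noisy_fit()
  d <- split_levels(rf$profile, rf$fit)
  expect_equal(rowSums(d$intensity), rf$profile$I, tolerance = 1e-15)
})

test_that("error shares recombine in quadrature to the experimental sigma", {
  rf <- ref_noisy_fit()
  d <- split_levels(rf$profile, rf$fit)
  # the identity holds wherever no level intensity was flagged negative
  bad <- unique(c(d$flags$negative[, "row"], d$flags$excluded))
  ok <- setdiff(seq_along(rf$profile$q), bad)
  expect_gt(length(ok), 50)
  expect_equal(rowSums(d$errors[ok, ]^2), rf$profile$sigma[ok]^2,
               tolerance = 1e-12)
  # worked identity: s_exp = 0.1, I_exp = 4, I_i = 1 -> s_i = 0.05
  p <- scattering_profile(c(0.01, 0.02), c(4, 4), c(0.1, 0.1))
  s <- scale_errors(p, cbind(c(1, 4), c(3, 0)))
  expect_equal(s[1, 1], 0.05)
  # I_i = I_exp gives back s_exp
  expect_equal(s[2, 1], 0.1)
})

test_that("on noise-free data the residual level equals the fitted curve", {
  m <- gox_reference_model(1)
  p <- simulate_unified(m, noise = noise_spec(fraction = 0, floor = 1e-4))
  f <- unified_fit(p, levels = 3, seed = 1)
  d <- split_levels(p, f)
  modelled <- predict(f, p$q, level = 1)
  expect_equal(d$intensity[, 1], modelled, tolerance = 1e-6)
})

test_that("upper levels are negligible at the high-q end of the window", {
  m <- gox_reference_model(1)
  q <- 0.3
  I1 <- level_intensity(q, m$levels[[1]])
  I2 <- level_intensity(q, m$levels[[2]])
  I3 <- level_intensity(q, m$levels[[3]])
  expect_lt(I2 / I1, 0.01)
  expect_lt(I3 / I1, 0.01)
})

test_that("demagnification: every rescaled level shows the monomer Rg", {
  rf <- ref_noisy_fit()
  d <- split_levels(rf$profile, rf$fit)
  Rg1 <- coef(rf$fit)[["Rg1"]]
  # lowest level: identity transform
  r1 <- rescale_q(d, 1, source = "data")
  keep <- is.finite(d$errors[, 1]) & d$errors[, 1] > 0
  expect_identical(r1$q, rf$profile$q[keep])
  for (lev in 2:3) {
    r <- rescale_q(d, lev)
    g <- guinier_fit(r, qrg_max = 1.0)
    expect_equal(g$Rg, Rg1, tolerance = 0.02)
  }
  # the demagnification factor itself
  rg <- coef(rf$fit)
  r3 <- rescale_q(d, 3, source = "data")
  expect_equal(r3$q[1] / rf$profile$q[1], rg[["Rg3"]] / rg[["Rg1"]],
               tolerance = 1e-12)
})

test_that("decomposition commutes with intensity recalibration", {
  rf <- ref_noisy_fit()
  d0 <- split_levels(rf$profile, rf$fit)
  c0 <- 3
  ps <- scattering_profile(rf$profile$q, c0 * rf$profile$I,
                           c0 * rf$profile$sigma)
  fs <- suppressWarnings(unified_fit(ps, levels = 3, seed = 3))
  ds <- split_levels(ps, fs)
  expect_equal(ds$intensity, c0 * d0$intensity, tolerance = 1e-5)
  expect_equal(ds$errors, c0 * d0$errors, tolerance = 1e-5)
})

test_that("decomposition refuses unusable fits", {
  rf <- ref_noisy_fit()
  f_bad <- rf$fit
  f_bad$converged <- FALSE
  expect_error(split_levels(rf$profile, f_bad), "converge")
  m1 <- unified_model(G = 3, Rg = 45, B = 1e-5, df = 3.6)
  p1 <- simulate_unified(m1, noise = noise_spec(fraction = 0, floor = 1e-6))
  f1 <- unified_fit(p1, levels = 1, fixed = numeric(0), seed = 2)
  expect_error(split_levels(p1, f1), "2 levels")
})
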