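test_that("noise-free simulation returns the exact forward curve", {
  m <- gox_reference_model(1)
  q <- default_q_grid()
  p <- simulate_unified(m, q, noise_spec(fraction = 0, floor = 1e-4))
  expect_identical(p$I, unified_intensity(q, m))
  expect_true(all(p$sigma == 1e-4))
})

test_that("simulation is deterministic under a seed, independent across seeds", {
  m <- gox_reference_model(2)
  n1 <- noise_spec(fraction = 0.02, seed = 11)
  a <- simulate_unified(m, noise = n1)
  b <- simulate_unified(m, noise = n1)
  expect_identical(a$I, b$I)
  cc <- simulate_unified(m, noise = noise_spec(fraction = 0.02, seed = 12))
  I0 <- unified_intensity(a$q, m)
  xi_a <- (a$I - I0) / (0.02 * I0)
  xi_c <- (cc$I - I0) / (0.02 * I0)
  expect_lt(abs(cor(xi_a, xi_c)), 0.2)
})

test_that("replicate means converge on the model (law of large numbers)", {
  m <- gox_reference_model(1)
  q <- c(0.004, 0.02, 0.1)
  I0 <- unified_intensity(q, m)
  sims <- sapply(1:500, function(s)
    simulate_unified(m, q, noise_spec(fraction = 0.02, seed = 1000 + s))$I)
  se <- 0.02 * I0 / sqrt(500)
  expect_true(all(abs(rowMeans(sims) - I0) < 3 * se))
})

test_that("sphere fixtures match their analytic fingerprints", {
  q <- default_q_grid(2000, qmin = 0.01, qmax = 0.4)
  p <- simulate_bead_target("sphere", R = 30, q = q)
  # first form-factor zero at q = 4.493/R
  i0 <- which.min(p$I[q < 0.2])
  expect_equal(q[i0], 4.493 / 30, tolerance = 0.01)
  # Guinier radius sqrt(3/5) R within 1 %
  g <- guinier_fit(restrict_q(p, qmax = 0.8 / (sqrt(3 / 5) * 30)),
                   qrg_max = 0.8)
  expect_equal(g$Rg, sqrt(3 / 5) * 30, tolerance = 0.01)
})

test_that("dumbbell and ellipsoid fixtures follow their closed forms", {
  q <- default_q_grid(100)
  amp <- function(x) ifelse(x < 1e-6, 1, 3 * (sin(x) - x * cos(x)) / x^3)
  d <- simulate_bead_target("dumbbell", R = 20, separation = 50, q = q)
  ref <- amp(q * 20)^2 * (2 + 2 * sin(q * 50) / (q * 50)) / 4
  expect_equal(d$I, ref, tolerance = 1e-12)
  # an aspect-1 ellipsoid is a sphere
  e1 <- simulate_bead_target("ellipsoid", R = 25, aspect = 1, q = q)
  s1 <- simulate_bead_target("sphere", R = 25, q = q)
  expect_equal(e1$I, s1$I, tolerance = 1e-6)
  # prolate ellipsoid Guinier radius: Rg^2 = (2 a^2 + c^2)/5
  e2 <- simulate_bead_target("ellipsoid", R = 20, aspect = 2, q = q)
  rg_true <- sqrt((2 * 20^2 + 40^2) / 5)
  g <- guinier_fit(restrict_q(e2, qmax = 1.0 / rg_true))
  expect_equal(g$Rg, rg_true, tolerance = 0.02)
  expect_error(simulate_bead_target("sphere", R = -1), "R > 0|positive|TRUE")
})
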