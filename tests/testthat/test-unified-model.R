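test_that("q* crossover has the right limits and frozen reference value", {
  # q Rg >> 1: erf saturates and q* collapses onto q
  expect_equal(qstar(10, 100), 10, tolerance = 1e-12)
  # frozen against an independent high-precision erf evaluation
  expect_equal(qstar(0.1, 25.5, k_sc = 1.06), 0.14605467403041619,
               tolerance = 1e-12)
  # q -> 0: the damped power-law term of a level must vanish
  lev <- unified_level(G = 0, Rg = 50, B = 1, df = 2.5)
  qsmall <- 10^seq(-3, -6, by = -1)
  I <- level_intensity(qsmall, lev)
  expect_true(all(diff(I) < 0))
  expect_lt(I[length(I)], 1e-12)
})

test_that("level intensity reproduces Guinier and power-law asymptotes", {
  # Guinier value at q = 1/Rg is exp(-1/3)
  lev <- unified_level(G = 1, Rg = 25.5, B = 0)
  expect_equal(level_intensity(1 / 25.5, lev), 0.71653131057378927,
               tolerance = 1e-12)
  # B = 0, q -> 0 recovers G
  expect_equal(level_intensity(1e-8, unified_level(G = 3.2, Rg = 40)), 3.2,
               tolerance = 1e-10)
  # pure power law at q Rg >> 1
  pl <- unified_level(G = 0, Rg = 10, B = 2, df = 2.4)
  q <- c(2, 4)
  expect_equal(level_intensity(q, pl), 2 * q^-2.4, tolerance = 1e-9)
  # log-log slope over q Rg > 10 equals -df within 0.5 %
  g1 <- unified_level(G = 1, Rg = 10, B = 1e-3, df = 3.1)
  q <- exp(seq(log(1.5), log(20), length.out = 50))
  slope <- coef(lm(log(level_intensity(q, g1)) ~ log(q)))[[2]]
  expect_equal(slope, -3.1, tolerance = 0.005)
})

test_that("a Guinier regression recovers each level's G and Rg within 1%", {
  for (Rg in c(12, 80, 400)) {
    lev <- unified_level(G = 5, Rg = Rg, B = 0)
    q <- exp(seq(log(0.05 / Rg), log(30 / Rg), length.out = 120))
    p <- scattering_profile(q, level_intensity(q, lev),
                            pmax(1e-8, 1e-4 * level_intensity(q, lev)))
    g <- guinier_fit(p, qrg_max = 1.0)
    expect_equal(g$Rg, Rg, tolerance = 0.01)
    expect_equal(g$G, 5, tolerance = 0.01)
  }
})

test_that("the multi-level model is additive, positive and ordered", {
  m <- gox_reference_model(1)
  q <- default_q_grid(100)
  # additivity: total = sum of level curves
  tot <- Reduce(`+`, lapply(m$levels, function(l) level_intensity(q, l)))
  expect_identical(unified_intensity(q, m), tot)
  # single-level model reduces to level_intensity
  m1 <- unified_model(G = 2, Rg = 30, B = 1e-4, df = 4)
  expect_identical(unified_intensity(q, m1),
                   level_intensity(q, m1$levels[[1]]))
  # splitting the stack in two preserves the sum
  mA <- unified_model(levels = m$levels[1:2])
  IB <- level_intensity(q, m$levels[[3]])
  expect_equal(unified_intensity(q, mA) + IB, unified_intensity(q, m),
               tolerance = 1e-14)
  expect_true(all(unified_intensity(q, m) > 0))
  # Rg ordering enforced at construction
  expect_error(unified_model(G = c(1, 1), Rg = c(100, 50)), "increasing")
  # cutoff radii are re-derived from the stack
  expect_equal(m$levels[[2]]$Rg_cutoff, m$levels[[1]]$Rg)
  expect_equal(m$levels[[1]]$Rg_cutoff, 0)
})

test_that("forward intensity at q -> 0 equals the sum of Guinier prefactors", {
  m1 <- gox_reference_model(1)
  expect_equal(unified_intensity(1e-8, m1), 86 + 0.09 + 0.0091,
               tolerance = 1e-9)
  expect_equal(gox_reference_model(2)$levels[[1]]$Rg, 26.2)
  expect_equal(gox_reference_model(2)$levels[[2]]$df, 2.86)
  expect_error(gox_reference_model(3), "unknown sample")
})

test_that("the reference 3-level curve is monotonically non-increasing", {
  m <- gox_reference_model(1)
  q <- default_q_grid(1000)
  expect_true(all(diff(unified_intensity(q, m)) <= 0))
})

test_that("model parameter files round trip", {
  m <- gox_reference_model(2)
  f <- withr::local_tempfile(fileext = ".txt")
  write_unified_params(m, f)
  m2 <- read_unified_params(f)
  expect_equal(coef(m2), coef(m), tolerance = 1e-15)
  expect_error(read_unified_params(withr::local_tempfile()), "not found")
})
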