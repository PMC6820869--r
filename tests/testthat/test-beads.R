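test_that("Debye sums match closed forms for 1- and 2-bead systems", {
  q <- default_q_grid(50)
  amp <- function(x) ifelse(x < 1e-6, 1, 3 * (sin(x) - x * cos(x)) / x^3)
  b1 <- bead_model(matrix(0, 1, 3), bead_radius = 10, Dmax = 30)
  expect_equal(debye_intensity(b1, q), amp(q * 10)^2, tolerance = 1e-12)
  d <- 25
  b2 <- bead_model(rbind(c(0, 0, 0), c(d, 0, 0)), bead_radius = 10, Dmax = 60)
  I2 <- amp(q * 10)^2 * (2 + 2 * sin(q * d) / (q * d))
  expect_equal(debye_intensity(b2, q), I2, tolerance = 1e-9)
})

test_that("a bead-filled sphere scatters like a sphere at low q", {
  sites <- bead_lattice(64, 2.5)
  expect_gt(nrow(sites), 1000)        # ~1200 beads at this resolution
  bs <- bead_model(sites, 2.5, 64)
  q <- exp(seq(log(0.002), log(0.05), length.out = 50))
  I <- debye_intensity(bs, q)         # binned path (N > 300)
  g <- guinier_fit(scattering_profile(q, I, 0.01 * I))
  expect_equal(g$Rg, sqrt(3 / 5) * 30, tolerance = 0.03)
})

test_that("lattice and model invariants are enforced", {
  sites <- bead_lattice(60, 2.5)
  # nearest-neighbour spacing is one bead diameter
  expect_equal(min(dist(sites[1:300, ])), 5, tolerance = 1e-9)
  # all sites inside the search sphere
  expect_true(all(rowSums(sites^2) <= (30 - 2.5)^2 * (1 + 1e-9)))
  expect_error(bead_model(rbind(c(0, 0, 0), c(1, 0, 0)), 2.5, 60),
               "overlap")
  expect_error(bead_model(matrix(c(40, 0, 0), 1), 2.5, 60), "outside")
})

test_that("annealing is reproducible and zero iterations keep the seed state", {
  tgt <- sphere_recons()$target
  a0 <- anneal_shape(tgt, 60, n_beads = 50, bead_radius = 3, seed = 9,
                     max_temps = 0)
  b0 <- anneal_shape(tgt, 60, n_beads = 50, bead_radius = 3, seed = 9,
                     max_temps = 0)
  expect_identical(a0$centers, b0$centers)   # untouched random start
  expect_equal(nrow(a0$centers), 50)
  expect_error(anneal_shape(tgt, 60, n_beads = 1e6), "capacity")
})

test_that("sphere reconstructions recover size and are mutually consistent", {
  sr <- sphere_recons()
  for (mdl in sr$models)
    expect_lt(abs(bead_rg(mdl) / sr$Rg_true - 1), 0.05)
  # roundness: principal axis ratio of a sphere reconstruction
  for (mdl in sr$models) {
    ev <- eigen(cov(mdl$centers), symmetric = TRUE)$values
    expect_gt(sqrt(ev[3] / ev[1]), 0.8)
  }
  expect_lt(nsd(sr$models[[1]], sr$models[[2]]), 1.0)
  # best-ever objective is bounded by the trace
  tr <- attr(sr$models[[1]], "trace")
  expect_lte(sr$models[[1]]$score, min(tr$objective))
})

test_that("NSD vanishes for identical and rigidly rotated models", {
  set.seed(4)
  sites <- bead_lattice(60, 2.5)
  pick <- sites[rowSums(sites^2) < 20^2, ]
  a <- bead_model(pick, 2.5, 60)
  expect_equal(nsd(a, a), 0, tolerance = 1e-12)
  th <- pi / 2
  Rz <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3,
               byrow = TRUE)
  b <- bead_model(pick %*% t(Rz), 2.5, 60)
  expect_lt(nsd(a, b), 1e-3)
})

test_that("averaging keeps the consensus and drops outliers", {
  sr <- sphere_recons()
  # averaging a model with itself returns that shape
  avg2 <- average_models(list(sr$models[[1]], sr$models[[1]]))
  expect_equal(nsd(avg2, sr$models[[1]]), 0, tolerance = 1e-6)
  # a thin rod among a set of sphere replicas is excluded by the NSD filter
  sites <- bead_lattice(60, 2)
  rod <- bead_model(sites[abs(sites[, 1]) < 4 & abs(sites[, 2]) < 4, ], 2, 60)
  pool <- c(rep(sr$models, 3), list(rod))
  avg <- average_models(pool)
  kept <- attr(avg, "kept")
  expect_false(kept[7])
  expect_true(all(kept[1:6]))
  expect_lt(abs(bead_rg(avg) / sr$Rg_true - 1), 0.05)
})

test_that("bead models export as dummy-atom PDB", {
  sr <- sphere_recons()
  f <- withr::local_tempfile(fileext = ".pdb")
  write_beads_pdb(sr$models[[1]], f)
  lines <- readLines(f)
  expect_equal(sum(grepl("^HETATM", lines)), nrow(sr$models[[1]]$centers))
  xyz <- as.numeric(substr(lines[grepl("^HETATM", lines)][1], 31, 38))
  expect_equal(xyz, unname(sr$models[[1]]$centers[1, 1]), tolerance = 1e-3)
})
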