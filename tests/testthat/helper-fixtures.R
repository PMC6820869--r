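# Shared fixtures, built in code and cached across test files (several are
# expensive: replicate fits, annealed reconstructions).

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# analytic sphere distance distribution, the p(r) oracle
sphere_pr <- function(r, R) {
  p <- r^2 * (1 - 0.75 * (r / R) + (1 / 16) * (r / R)^3)
  p[r > 2 * R] <- 0
  p
}

# area-normalised root-mean-square deviation, relative to the peak
nrms <- function(r, a, b) {
  a <- a / pracma::trapz(r, a)
  b <- b / pracma::trapz(r, b)
  sqrt(mean((a - b)^2)) / max(abs(b))
}

# one noisy reference dataset + its fit, reused by decomposition/rescaling
ref_noisy_fit <- function() cached("ref_noisy_fit", {
  m <- gox_reference_model(1)
  p <- simulate_unified(m, noise = noise_spec(fraction = 0.02, seed = 3))
  f <- suppressWarnings(unified_fit(p, levels = 3, seed = 3))
  list(model = m, profile = p, fit = f)
})

# 25 replicate fits at the default study conditions (2 % noise)
replicate_fits <- function() cached("replicate_fits", {
  m <- gox_reference_model(1)
  truth <- coef(m)
  fits <- lapply(1:25, function(s) {
    p <- simulate_unified(m, noise = noise_spec(fraction = 0.02, seed = s))
    suppressWarnings(unified_fit(p, levels = 3, seed = s))
  })
  list(truth = truth, fits = fits,
       free = c("G1", "Rg1", "G2", "Rg2", "B2", "df2", "G3", "Rg3", "B3"))
})

# two seeded sphere reconstructions (shortened schedule, small lattice)
sphere_recons <- function() cached("sphere_recons", {
  tgt <- simulate_bead_target("sphere", R = 30, q = default_q_grid(150),
                              noise = noise_spec(fraction = 0.02,
                                                 floor = 1e-4, seed = 2))
  mods <- lapply(1:2, function(s)
    anneal_shape(tgt, Dmax = 60, n_beads = 300, bead_radius = 2, seed = s,
                 moves_per_temp = 15000, cooling = 0.95))
  list(target = tgt, models = mods, Rg_true = sqrt(3 / 5) * 30)
})
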