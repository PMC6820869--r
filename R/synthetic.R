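#' Default instrument q grid
#'
#' 200 log-spaced points on 0.003-0.5 1/Angstrom, the pinhole-SANS window
#' (three detector distances) over which the hierarchical curves analysed by
#' this package were measured.
#'
#' @param n number of points.
#' @param qmin,qmax window bounds, 1/Angstrom.
#' @export
default_q_grid <- function(n = 200, qmin = 0.003, qmax = 0.5)
  logspace(qmin, qmax, n)

#' Noise specification for simulated profiles
#'
#' `"multiplicative_gaussian"` draws `I_sim = I (1 + fraction * xi)` with
#' standard normal `xi` and reports `sigma = max(fraction * I, floor)`;
#' `"poisson_like"` lets the relative error grow as intensity falls
#' (`sd = fraction * sqrt(I * max(I))`), mimicking counting statistics at
#' fixed acquisition time.
#'
#' @param model noise model.
#' @param fraction relative noise level (0.02 = 2 percent).
#' @param floor absolute sigma floor, 1/cm.
#' @param seed optional integer seed applied at simulation time.
#' @export
noise_spec <- function(model = c("multiplicative_gaussian", "poisson_like"),
                       fraction = 0.02, floor = 1e-4, seed = NULL) {
  model <- match.arg(model)
  stopifnot(fraction >= 0, floor >= 0)
  structure(list(model = model, fraction = fraction, floor = floor, seed = seed),
            class = "noise_spec")
}

#' Simulate a scattering profile from a Unified model
#'
#' Evaluates the forward Unified curve on `q` and applies the noise model.
#' With `fraction = 0` the exact curve is returned with `sigma` at the
#' floor. Identical seeds give identical profiles.
#'
#' @param model a [unified_model()].
#' @param q evaluation grid, 1/Angstrom.
#' @param noise a [noise_spec()].
#' @param label profile label.
#' @return A [scattering_profile()].
#' @export
simulate_unified <- function(model, q = default_q_grid(),
                             noise = noise_spec(), label = "simulated") {
  stopifnot(inherits(model, "unified_model"), inherits(noise, "noise_spec"))
  I_true <- unified_intensity(q, model)
  if (!is.null(noise$seed)) set.seed(noise$seed)
  if (noise$model == "multiplicative_gaussian") {
    sig <- pmax(noise$fraction * I_true, noise$floor)
    I_sim <- if (noise$fraction > 0)
      I_true * (1 + noise$fraction * stats::rnorm(length(q))) else I_true
  } else {
    sig <- pmax(noise$fraction * sqrt(I_true * max(I_true)), noise$floor)
    I_sim <- if (noise$fraction > 0) I_true + sig * stats::rnorm(length(q)) else I_true
  }
  scattering_profile(q, I_sim, sig, label = label, sort = FALSE)
}

#' Published 3-level parameter sets for the GOx-graphene sensor samples
#'
#' Central values of the 3-level Unified fits to the two glucose-oxidase /
#' single-layer-graphene sensor materials (sample 1 functionalised at pH 7,
#' sample 2 at pH 9): levels are the GOx dimer, the mass-fractal aggregate
#' and the surface-bounded cluster, smallest first. The lowest level carries
#' no power-law term and the cluster exponent is the Porod value 4.
#'
#' @param sample 1 (pH 7) or 2 (pH 9).
#' @return A [unified_model()].
#' @examples
#' coef(gox_reference_model(1))
#' @export
gox_reference_model <- function(sample = 1) {
  if (!sample %in% c(1, 2)) stop("unknown sample id: ", sample)
  if (sample == 1)
    unified_model(G = c(91e-4, 9e-2, 86), Rg = c(25.5, 110, 590),
                  B = c(0, 1.7e-6, 43.3e-10), df = c(4, 2.34, 4))
  else
    unified_model(G = c(71e-4, 12e-2, 33), Rg = c(26.2, 108, 550),
                  B = c(0, 2.6e-7, 23.6e-10), df = c(4, 2.86, 4))
}

#' Simulate scattering from simple reference shapes
#'
#' Analytic form factors for fixtures and oracles: a homogeneous sphere, an
#' orientationally averaged ellipsoid of revolution, or a dumbbell of two
#' spheres (Debye cross term). Intensities are normalised to `I0` at q = 0
#' and noised through [noise_spec()].
#'
#' @param shape `"sphere"`, `"ellipsoid"` or `"dumbbell"`.
#' @param R sphere radius / ellipsoid equatorial semi-axis, Angstrom.
#' @param aspect ellipsoid axial ratio c/a.
#' @param separation dumbbell centre-to-centre distance, Angstrom.
#' @param I0 forward intensity, 1/cm.
#' @param q evaluation grid.
#' @param noise a [noise_spec()] (noise-free by default).
#' @param label profile label.
#' @return A [scattering_profile()].
#' @export
simulate_bead_target <- function(shape = c("sphere", "ellipsoid", "dumbbell"),
                                 R = 30, aspect = 2, separation = 2 * R,
                                 I0 = 1, q = default_q_grid(),
                                 noise = noise_spec(fraction = 0, floor = 1e-6),
                                 label = NULL) {
  shape <- match.arg(shape)
  stopifnot(R > 0, aspect > 0, separation >= 0)
  amp <- function(x) ifelse(x < 1e-6, 1 - x^2 / 10,
                            3 * (sin(x) - x * cos(x)) / x^3)
  I_rel <- switch(shape,
    sphere = amp(q * R)^2,
    ellipsoid = {
      # orientational average over the angle between q and the symmetry axis
      u <- (seq_len(64) - 0.5) / 64
      reff <- sqrt(R^2 * (1 - u^2) + (aspect * R)^2 * u^2)
      rowMeans(outer(q, reff, function(qq, rr) amp(qq * rr)^2))
    },
    dumbbell = amp(q * R)^2 * (2 + 2 * sinc(q * separation)) / 4)
  if (is.null(label)) label <- paste("synthetic", shape)
  I_true <- I0 * I_rel
  if (!is.null(noise$seed)) set.seed(noise$seed)
  if (noise$model == "multiplicative_gaussian") {
    sig <- pmax(noise$fraction * abs(I_true), noise$floor)
    I_sim <- if (noise$fraction > 0)
      I_true * (1 + noise$fraction * stats::rnorm(length(q))) else I_true
  } else {
    sig <- pmax(noise$fraction * sqrt(abs(I_true) * max(I_true)), noise$floor)
    I_sim <- if (noise$fraction > 0) I_true + sig * stats::rnorm(length(q)) else I_true
  }
  scattering_profile(q, I_sim, sig, label = label, sort = FALSE)
}
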