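#' Hexagonal close-packed lattice inside a search sphere
#'
#' Generates the candidate bead sites of a reconstruction: an HCP lattice
#' with nearest-neighbour spacing `2 * bead_radius`, centred at the origin,
#' keeping sites whose beads lie entirely inside the sphere of diameter
#' `Dmax`.
#'
#' @param Dmax search sphere diameter, Angstrom.
#' @param bead_radius bead radius, Angstrom.
#' @return Matrix of site coordinates (columns x, y, z).
#' @export
bead_lattice <- function(Dmax, bead_radius) {
  stopifnot(Dmax > 0, bead_radius > 0, Dmax > 4 * bead_radius)
  a <- 2 * bead_radius
  h <- a * sqrt(2 / 3)                 # close-packed interlayer distance
  Rmax <- Dmax / 2 - bead_radius
  nk <- ceiling(Rmax / h); nj <- ceiling(Rmax / (a * sqrt(3) / 2)); ni <- ceiling(Rmax / a) + 1
  grid <- expand.grid(i = -ni:ni, j = -nj:nj, k = -nk:nk)
  odd <- grid$k %% 2 != 0
  x <- a * (grid$i + 0.5 * grid$j) + ifelse(odd, a / 2, 0)
  y <- a * sqrt(3) / 2 * grid$j + ifelse(odd, a / (2 * sqrt(3)), 0)
  z <- h * grid$k
  keep <- x^2 + y^2 + z^2 <= Rmax^2
  cbind(x = x[keep], y = y[keep], z = z[keep])
}

#' Dummy-bead shape model
#'
#' A low-resolution shape represented as identical spherical beads on a
#' close-packed lattice, the standard dummy-atom representation of small-
#' angle scattering envelopes. Invariants checked on construction: all
#' beads inside the search sphere of diameter `Dmax`, and no two beads
#' closer than one bead diameter (within lattice tolerance).
#'
#' @param centers matrix of bead centres (columns x, y, z), Angstrom.
#' @param bead_radius bead radius, Angstrom.
#' @param Dmax search sphere diameter, Angstrom.
#' @param lattice packing tag.
#' @param score objective value of the producing search, if any.
#' @return An object of class `bead_model`.
#' @export
bead_model <- function(centers, bead_radius, Dmax, lattice = "hcp",
                       score = NA_real_) {
  centers <- as.matrix(centers)
  stopifnot(ncol(centers) == 3, nrow(centers) >= 1, bead_radius > 0, Dmax > 0)
  if (max(rowSums(centers^2)) > (Dmax / 2)^2 * (1 + 1e-6))
    stop("bead centre outside the search sphere of diameter Dmax")
  if (nrow(centers) > 1 && nrow(centers) <= 2000) {
    if (min(stats::dist(centers)) < 2 * bead_radius * (1 - 1e-9))
      stop("overlapping beads: pair closer than one bead diameter")
  }
  structure(list(centers = centers, bead_radius = bead_radius, Dmax = Dmax,
                 lattice = lattice, score = score),
            class = "bead_model")
}

#' @export
print.bead_model <- function(x, ...) {
  cat(sprintf("bead model: %d beads of radius %.3g A on a %s lattice (Dmax = %.4g A)\n",
              nrow(x$centers), x$bead_radius, x$lattice, x$Dmax))
  cat(sprintf("  Rg = %.4g A", bead_rg(x)))
  if (is.finite(x$score)) cat(sprintf(", search objective = %.4g", x$score))
  cat("\n")
  invisible(x)
}

#' Radius of gyration of a bead model
#'
#' Includes the beads' own gyration term: `Rg^2 = <|x - xbar|^2> +
#' (3/5) bead_radius^2`.
#'
#' @param model a [bead_model()].
#' @export
bead_rg <- function(model) {
  X <- sweep(model$centers, 2, colMeans(model$centers))
  sqrt(mean(rowSums(X^2)) + 0.6 * model$bead_radius^2)
}

.sphere_amp <- function(x) ifelse(x < 1e-6, 1 - x^2 / 10,
                                  3 * (sin(x) - x * cos(x)) / x^3)

#' Debye scattering of a bead model
#'
#' `I(q) = f(q)^2 sum_jk sinc(q d_jk)` with the spherical-bead form-factor
#' amplitude `f`; the O(N^2) pair sum is accelerated by distance binning
#' (bin width `bead_radius / 4`) above 300 beads and evaluated exactly
#' below.
#'
#' @param model a [bead_model()].
#' @param q evaluation grid, 1/Angstrom.
#' @return Relative intensity (arbitrary scale; `I(0) = N^2 f(0)^2`).
#' @export
debye_intensity <- function(model, q) {
  stopifnot(inherits(model, "bead_model"), nrow(model$centers) >= 1)
  ctr <- sweep(model$centers, 2, colMeans(model$centers))
  S <- cpp_debye_sum(ctr, q, bin_width = model$bead_radius / 4)
  .sphere_amp(q * model$bead_radius)^2 * S
}

.anneal_target <- function(target, bead_radius, n_q, q_max) {
  if (is.null(q_max)) q_max <- pi / (2 * bead_radius)
  if (inherits(target, "scattering_profile")) {
    p <- restrict_q(target, qmax = q_max)
    if (length(p$q) > n_q) {
      want <- logspace(min(p$q), max(p$q), n_q)
      idx <- unique(vapply(want, function(w) which.min(abs(log(p$q) - log(w))), 0L))
      p <- scattering_profile(p$q[idx], p$I[idx], p$sigma[idx], sort = FALSE)
    }
    list(q = p$q, I = p$I, sigma = p$sigma)
  } else if (inherits(target, "pofr")) {
    q <- logspace(0.2 / target$Rg, min(q_max, 10 / target$Rg), n_q)
    I <- forward_intensity(target, q)
    list(q = q, I = I, sigma = 0.01 * abs(I) + 1e-6 * max(abs(I)))
  } else stop("target must be a scattering_profile or a pofr")
}

#' Reconstruct a bead shape by simulated annealing
#'
#' A desk-scale dummy-atom reconstruction: beads on an HCP lattice inside
#' the `Dmax` sphere are toggled by single-bead-flip Metropolis annealing to
#' minimise the chi-square between the (scale-free) Debye curve of the model
#' and the target intensity, plus a compactness prior (penalty on isolated
#' beads and on unsaturated neighbour shells) that plays the role of the
#' connectivity bias of classical dummy-atom modelling. The intensity scale
#' factor is solved analytically at every evaluation, the cooling schedule
#' is geometric, and the search stops when the acceptance rate falls below
#' `min_accept`. Runs are reproducible at a fixed `seed`.
#'
#' @param target a [scattering_profile()], or a [pofr()] whose regenerated
#'   intensity is fitted.
#' @param Dmax search sphere diameter, Angstrom.
#' @param n_beads number of beads switched on initially (at random).
#' @param bead_radius bead radius; default `Dmax / 40`.
#' @param compactness_weight weight of the compactness prior.
#' @param T0 initial temperature; `NULL` calibrates it from typical move
#'   magnitudes.
#' @param cooling geometric cooling factor per temperature step.
#' @param moves_per_temp proposals per temperature; default `100 * n_beads`.
#' @param max_temps maximum temperature steps; 0 returns the seeded random
#'   initial configuration unchanged.
#' @param min_accept acceptance-rate stopping threshold.
#' @param seed integer seed.
#' @param n_q number of target q points used (log-subsampled).
#' @param q_max target curve cut-off; default `pi / (2 bead_radius)` (finer
#'   features than the beads cannot be represented).
#' @return A [bead_model()]; attributes `"chi2_reduced"` and `"trace"`
#'   carry the fit quality of the best model and the annealing trace.
#' @export
anneal_shape <- function(target, Dmax, n_beads = 500, bead_radius = Dmax / 40,
                         compactness_weight = 0.05, T0 = NULL, cooling = 0.98,
                         moves_per_temp = NULL, max_temps = 400,
                         min_accept = 0.001, seed = NULL, n_q = 40,
                         q_max = NULL) {
  stopifnot(Dmax > 0, n_beads >= 1, cooling > 0, cooling < 1)
  sites <- bead_lattice(Dmax, bead_radius)
  M <- nrow(sites)
  if (n_beads > M)
    stop("n_beads (", n_beads, ") exceeds lattice capacity (", M, " sites)")
  if (is.null(moves_per_temp)) moves_per_temp <- 100 * n_beads
  if (moves_per_temp < 0) stop("invalid schedule: moves_per_temp < 0")
  tgt <- .anneal_target(target, bead_radius, n_q, q_max)
  if (!is.null(seed)) set.seed(seed)
  occ0 <- integer(M)
  occ0[sample.int(M, n_beads)] <- 1L
  if (max_temps == 0 || moves_per_temp == 0) {
    return(bead_model(sites[occ0 == 1L, , drop = FALSE], bead_radius, Dmax,
                      score = NA_real_))
  }
  nb <- cpp_neighbors(sites, cutoff = 2 * bead_radius * 1.05)
  ff <- .sphere_amp(tgt$q * bead_radius)^2
  res <- cpp_anneal(sites, nb$ptr, nb$idx, occ0, tgt$q, tgt$I, tgt$sigma, ff,
                    bin_width = bead_radius / 4,
                    w_compact = compactness_weight,
                    T0 = if (is.null(T0)) -1 else T0, cooling = cooling,
                    moves_per_round = as.integer(moves_per_temp),
                    max_rounds = as.integer(max_temps),
                    min_accept = min_accept)
  out <- bead_model(sites[res$occupancy == 1L, , drop = FALSE], bead_radius,
                    Dmax, score = res$best_objective)
  attr(out, "chi2_reduced") <- res$best_chi2
  attr(out, "trace") <- data.frame(objective = res$trace_objective,
                                   acceptance = res$trace_acceptance,
                                   temperature = res$trace_temperature)
  out
}

.rot3 <- function(ang) {
  c1 <- cos(ang[1]); s1 <- sin(ang[1])
  c2 <- cos(ang[2]); s2 <- sin(ang[2])
  c3 <- cos(ang[3]); s3 <- sin(ang[3])
  matrix(c(c2 * c3, c2 * s3, -s2,
           s1 * s2 * c3 - c1 * s3, s1 * s2 * s3 + c1 * c3, s1 * c2,
           c1 * s2 * c3 + s1 * s3, c1 * s2 * s3 - s1 * c3, c1 * c2),
         3, 3, byrow = TRUE)
}

.nsd_raw <- function(A, B, dA, dB) {
  sqrt(0.5 * (mean(cpp_min_dist2(A, B)) / dB^2 +
              mean(cpp_min_dist2(B, A)) / dA^2))
}

# Align B onto A (principal axes + sign flips, then local rigid-body
# refinement) and return the aligned coordinates and the NSD value.
.nsd_align <- function(A, B, dA, dB, refine = TRUE) {
  muA <- colMeans(A)
  A0 <- sweep(A, 2, muA)
  B0 <- sweep(B, 2, colMeans(B))
  frame <- function(X) {
    e <- eigen(stats::cov(X), symmetric = TRUE)$vectors
    if (det(e) < 0) e[, 3] <- -e[, 3]
    e
  }
  Ra <- frame(A0)
  A1 <- A0 %*% Ra
  Bf <- B0 %*% frame(B0)
  best <- list(nsd = Inf, X = NULL)
  for (sx in c(1, -1)) for (sy in c(1, -1)) for (sz in c(1, -1)) {
    Bt <- Bf %*% diag(c(sx, sy, sz))
    v <- .nsd_raw(A1, Bt, dA, dB)
    if (v < best$nsd) best <- list(nsd = v, X = Bt)
  }
  if (refine && best$nsd > 0) {
    obj <- function(par) {
      Bt <- best$X %*% .rot3(par[1:3])
      Bt <- sweep(Bt, 2, par[4:6], `+`)
      .nsd_raw(A1, Bt, dA, dB)
    }
    op <- stats::optim(rep(0, 6), obj, method = "Nelder-Mead",
                       control = list(maxit = 300, reltol = 1e-6))
    if (op$value < best$nsd) {
      Bt <- best$X %*% .rot3(op$par[1:3])
      Bt <- sweep(Bt, 2, op$par[4:6], `+`)
      best <- list(nsd = op$value, X = Bt)
    }
  }
  # B_in_A: aligned copy of B expressed in A's original frame
  list(nsd = best$nsd, A = A1, B = best$X,
       B_in_A = sweep(best$X %*% t(Ra), 2, muA, `+`))
}

#' Normalized spatial discrepancy between bead models
#'
#' The standard superposition metric of dummy-atom shapes: the symmetrised
#' mean nearest-neighbour distance between the two bead sets, normalised by
#' their lattice spacings, minimised over rigid rotations/translations
#' (principal-axes superposition with sign flips, then Nelder-Mead
#' refinement). 0 for identical shapes; values below 1 conventionally mean
#' "similar".
#'
#' @param a,b [bead_model()]s.
#' @param refine run the local rigid-body refinement (default).
#' @return The NSD value (dimensionless).
#' @export
nsd <- function(a, b, refine = TRUE) {
  stopifnot(inherits(a, "bead_model"), inherits(b, "bead_model"),
            nrow(a$centers) >= 1, nrow(b$centers) >= 1)
  .nsd_align(a$centers, b$centers, 2 * a$bead_radius, 2 * b$bead_radius,
             refine = refine)$nsd
}

#' Average a set of replicate bead reconstructions
#'
#' Picks the reconstruction with the lowest mean NSD to the others as
#' reference, discards outliers (mean NSD above mean + 2 sd across models),
#' aligns the remaining models onto the reference, accumulates bead
#' occupancy on the reference lattice and keeps sites at or above half the
#' maximum occupancy -- a simplified pairwise analogue of the usual
#' sort/align/average protocol for dummy-atom model sets.
#'
#' @param models list of at least 2 [bead_model()]s sharing bead radius.
#' @param occupancy_threshold fraction of the maximum occupancy retained.
#' @return A [bead_model()]; attributes `"occupancy"` (per-site counts),
#'   `"kept"` (logical per input model) and `"mean_nsd"`.
#' @export
average_models <- function(models, occupancy_threshold = 0.5) {
  stopifnot(is.list(models), length(models) >= 2,
            all(vapply(models, inherits, TRUE, "bead_model")))
  n <- length(models)
  nsd_mat <- matrix(0, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    nsd_mat[i, j] <- nsd_mat[j, i] <- nsd(models[[i]], models[[j]])
  mean_nsd <- rowSums(nsd_mat) / (n - 1)
  ref <- which.min(mean_nsd)
  cut <- mean(mean_nsd) + 2 * stats::sd(mean_nsd)
  kept <- mean_nsd <= cut | seq_len(n) == ref
  refm <- models[[ref]]
  sites <- bead_lattice(refm$Dmax, refm$bead_radius)
  # accumulate occupancy in the reference's own (lattice-aligned) frame
  counts <- integer(nrow(sites))
  nearest_site <- function(X) {
    d2 <- outer(rowSums(X^2), rep(1, nrow(sites))) +
      outer(rep(1, nrow(X)), rowSums(sites^2)) - 2 * X %*% t(sites)
    max.col(-d2)
  }
  for (i in which(kept)) {
    al <- .nsd_align(refm$centers, models[[i]]$centers,
                     2 * refm$bead_radius, 2 * models[[i]]$bead_radius)
    idx <- nearest_site(al$B_in_A)
    counts[unique(idx)] <- counts[unique(idx)] + 1L
  }
  keep_sites <- counts >= occupancy_threshold * max(counts)
  out <- bead_model(sites[keep_sites, , drop = FALSE], refm$bead_radius,
                    refm$Dmax, lattice = refm$lattice)
  attr(out, "occupancy") <- counts
  attr(out, "kept") <- kept
  attr(out, "mean_nsd") <- mean_nsd
  out
}

#' Write a bead model as a dummy-atom PDB
#'
#' One HETATM carbon per bead (residue DUM), the conventional exchange
#' format for viewing dummy-atom envelopes.
#'
#' @param model a [bead_model()].
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
write_beads_pdb <- function(model, path) {
  stopifnot(inherits(model, "bead_model"))
  con <- file(path, "wt")
  on.exit(close(con))
  writeLines(sprintf("REMARK dummy-bead model, %d beads, radius %.3f A, Dmax %.2f A",
                     nrow(model$centers), model$bead_radius, model$Dmax), con)
  for (i in seq_len(nrow(model$centers))) {
    writeLines(sprintf("HETATM%5d  C   DUM A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
                       i %% 100000, i %% 10000, model$centers[i, 1],
                       model$centers[i, 2], model$centers[i, 3]), con)
  }
  writeLines("END", con)
  invisible(path)
}
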