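#' Separate a fitted total intensity into per-level curves
#'
#' The fitted upper levels (all but the smallest) are evaluated from their
#' Unified parameters and subtracted from the *experimental* intensity; the
#' lowest level is the residual, so the per-level curves sum to the data
#' exactly at every point and real-data features survive in the monomer
#' curve for downstream shape modelling. (`lowest_from = "model"` replaces
#' the residual by the fitted lowest-level formula for noise-free work.)
#' Experimental errors are distributed over levels with [scale_errors()].
#'
#' @param profile the measured [scattering_profile()].
#' @param fit a converged [unified_fit()] of that profile.
#' @param lowest_from `"residual"` (default) or `"model"`.
#' @return An object of class `level_decomposition`: list with the source
#'   `profile`, `fit`, `intensity` (matrix, one column per level, smallest
#'   first), `errors` (same shape, from [scale_errors()]), and `flags`
#'   (indices of negative residual points and of excluded points with
#'   non-positive experimental intensity).
#' @export
split_levels <- function(profile, fit, lowest_from = c("residual", "model")) {
  stopifnot(inherits(profile, "scattering_profile"), inherits(fit, "unified_fit"))
  lowest_from <- match.arg(lowest_from)
  if (!fit$converged) stop("fit did not converge; refusing to decompose")
  n <- n_levels(fit$model)
  if (n < 2) stop("decomposition requires at least 2 levels")
  q <- profile$q
  I_mat <- matrix(NA_real_, length(q), n,
                  dimnames = list(NULL, paste0("level", seq_len(n))))
  for (i in 2:n) I_mat[, i] <- predict(fit, q, level = i)
  I_mat[, 1] <- if (lowest_from == "residual")
    profile$I - rowSums(I_mat[, -1, drop = FALSE])
  else predict(fit, q, level = 1)
  s_mat <- scale_errors(profile, I_mat)
  flags <- list(negative = which(I_mat < 0, arr.ind = TRUE),
                excluded = which(profile$I <= 0))
  structure(list(profile = profile, fit = fit, intensity = I_mat,
                 errors = s_mat, flags = flags, lowest_from = lowest_from),
            class = "level_decomposition")
}

#' Distribute experimental errors over decomposed levels
#'
#' Per-level uncertainties are the experimental errors shared in proportion
#' to each level's intensity fraction, `s_i = sqrt(s_exp^2 * I_i / I_exp)`,
#' so that `sum_i s_i^2 = s_exp^2` wherever the level intensities sum to the
#' experimental one. Negative level intensities (noise-driven residuals)
#' enter with their absolute value; points with non-positive experimental
#' intensity are excluded (NA).
#'
#' @param profile the measured [scattering_profile()].
#' @param intensity matrix of per-level intensities (rows = q points).
#' @return Matrix of per-level 1-sigma errors, same shape as `intensity`.
#' @export
scale_errors <- function(profile, intensity) {
  stopifnot(inherits(profile, "scattering_profile"),
            nrow(intensity) == length(profile$q))
  s2 <- profile$sigma^2
  out <- sqrt(s2 * abs(intensity) / profile$I)
  out[profile$I <= 0, ] <- NA_real_
  out
}

#' @export
print.level_decomposition <- function(x, ...) {
  n <- ncol(x$intensity)
  cat(sprintf("level decomposition: %d levels over %d q points\n",
              n, nrow(x$intensity)))
  cat(sprintf("  lowest level from: %s\n", x$lowest_from))
  if (nrow(x$flags$negative))
    cat(sprintf("  %d negative level-intensity point(s) flagged\n",
                nrow(x$flags$negative)))
  if (length(x$flags$excluded))
    cat(sprintf("  %d point(s) excluded (non-positive experimental I)\n",
                length(x$flags$excluded)))
  invisible(x)
}

#' Demagnify an upper structural level onto the monomer q scale
#'
#' Stretches the q axis of level `i` by `Rg_i / Rg_1` so that the level's
#' Guinier knee lands where the smallest (monomer) level's knee sits: a
#' Guinier analysis of the rescaled curve returns an apparent radius equal
#' to the monomer `Rg_1`. This demagnification lets upper-level curves feed
#' monomer-scale real-space modelling (the search volume of a bead
#' reconstruction), at the cost of a resolution coarsening proportional to
#' the level's size. Intensities (and their scaled errors) are carried over
#' unchanged; for the lowest level the transform is the identity.
#'
#' With `source = "fit"` (the choice intended for shape modelling) the level
#' intensity is evaluated from its fitted parameters on a dense log grid
#' spanning the level's Guinier-to-power-law range, and errors follow the
#' experimental error model interpolated onto that grid; `source = "data"`
#' rescales the decomposed data columns as they stand.
#'
#' @param decomposition a [split_levels()] result.
#' @param level level index (1 = smallest).
#' @param source `"fit"` or `"data"`.
#' @param n grid size for `source = "fit"`.
#' @return A [scattering_profile()] on the demagnified axis.
#' @export
rescale_q <- function(decomposition, level, source = c("fit", "data"), n = 200) {
  stopifnot(inherits(decomposition, "level_decomposition"))
  source <- match.arg(source)
  fit <- decomposition$fit
  nl <- n_levels(fit$model)
  stopifnot(level >= 1, level <= nl)
  Rg_i <- fit$model$levels[[level]]$Rg
  Rg_1 <- fit$model$levels[[1]]$Rg
  if (Rg_i <= 0 || Rg_1 <= 0) stop("non-positive Rg")
  m <- Rg_i / Rg_1   # demagnification factor, >= 1 for upper levels
  prof <- decomposition$profile
  if (source == "data") {
    q <- prof$q
    I <- decomposition$intensity[, level]
    s <- decomposition$errors[, level]
    ok <- is.finite(s) & s > 0
    q <- q[ok]; I <- I[ok]; s <- s[ok]
  } else {
    q <- logspace(0.05 / Rg_i, 10 / Rg_i, n)
    I <- predict(fit, q, level = level)
    # experimental error model carried onto the synthetic grid
    lqd <- log(prof$q)
    s_exp <- exp(stats::approx(lqd, log(prof$sigma), xout = log(q), rule = 2)$y)
    I_exp <- exp(stats::approx(lqd, log(pmax(prof$I, 1e-12 * max(prof$I))),
                               xout = log(q), rule = 2)$y)
    s <- sqrt(s_exp^2 * pmin(abs(I) / I_exp, 1))
  }
  scattering_profile(q * m, I, s,
                     label = sprintf("level %d demagnified x%.4g", level, m),
                     sort = FALSE)
}
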