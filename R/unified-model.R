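#' Error-function-modified scattering vector of the Unified model
#'
#' The Unified scattering function joins each level's Guinier and power-law
#' regimes through the crossover variable
#' `q* = q / erf(q k_sc Rg / sqrt(6))^3` with `k_sc` approximately 1.06.
#' `q* -> q` for `q Rg >> 1` and diverges as `q -> 0`, which damps the
#' power-law term below the Guinier knee.
#'
#' @param q scattering vector, 1/Angstrom (positive).
#' @param Rg radius of gyration of the level, Angstrom.
#' @param k_sc crossover constant, default 1.06.
#' @return `q*` in 1/Angstrom.
#' @export
qstar <- function(q, Rg, k_sc = 1.06) {
  stopifnot(all(q > 0), Rg > 0)
  q / erf(q * k_sc * Rg / sqrt(6))^3
}

#' One structural level of a Unified scattering model
#'
#' A level contributes `G exp(-q^2 Rg^2 / 3) +
#' B exp(-q^2 Rg_cutoff^2 / 3) (q*)^(-df)` to the total intensity, where
#' `Rg_cutoff` is the radius of gyration of the next-lower level (0 for the
#' lowest) and damps the power law at the length scale where the smaller
#' structure takes over. The power-law factor is evaluated as
#' `erf(...)^(3 df) q^(-df)` so it underflows gracefully instead of
#' overflowing at small q.
#'
#' @param G Guinier prefactor, 1/cm (>= 0).
#' @param Rg radius of gyration, Angstrom (> 0).
#' @param B power-law prefactor, 1/cm/Angstrom^(-df) (>= 0).
#' @param df power-law exponent in (0, 4]; 4 is the Porod limit of a smooth,
#'   well-defined surface, non-integer values indicate fractal organisation.
#' @param k_sc crossover constant.
#' @param Rg_cutoff damping radius, Angstrom (0 disables damping).
#' @return An object of class `unified_level`.
#' @export
unified_level <- function(G, Rg, B = 0, df = 4, k_sc = 1.06, Rg_cutoff = 0) {
  stopifnot(G >= 0, Rg > 0, B >= 0, df > 0, df <= 4, k_sc > 0, Rg_cutoff >= 0)
  if (Rg_cutoff > 0 && Rg_cutoff >= Rg)
    stop("Rg_cutoff must be smaller than Rg")
  structure(list(G = G, Rg = Rg, B = B, df = df, k_sc = k_sc,
                 Rg_cutoff = Rg_cutoff),
            class = "unified_level")
}

#' Intensity of a single Unified level
#'
#' @param q scattering vector grid, 1/Angstrom.
#' @param level a [unified_level()].
#' @return Intensity in 1/cm.
#' @export
level_intensity <- function(q, level) {
  stopifnot(inherits(level, "unified_level"), all(q > 0))
  guinier <- level$G * exp(-q^2 * level$Rg^2 / 3)
  if (level$B > 0) {
    e <- erf(q * level$k_sc * level$Rg / sqrt(6))
    damp <- if (level$Rg_cutoff > 0) exp(-q^2 * level$Rg_cutoff^2 / 3) else 1
    pl <- level$B * damp * e^(3 * level$df) * q^(-level$df)
  } else {
    pl <- 0
  }
  guinier + pl
}

#' Multi-level Unified scattering model
#'
#' Builds an ordered stack of [unified_level()]s, smallest structure first.
#' Parameters are given as vectors over levels (`B` and `df` recycle).
#' Radii of gyration must be strictly increasing, and each level's power-law
#' damping radius is set to the radius of the level below it (0 for the
#' lowest level), the convention under which a 3-level stack describes
#' monomer / aggregate / cluster hierarchies.
#'
#' @param G Guinier prefactors, 1/cm, smallest level first.
#' @param Rg radii of gyration, Angstrom, strictly increasing.
#' @param B power-law prefactors (recycled).
#' @param df power-law exponents (recycled).
#' @param k_sc crossover constant(s) (recycled).
#' @param levels alternatively, a list of [unified_level()]s (overrides the
#'   vector arguments); cutoff radii are re-derived from the stack order.
#' @return An object of class `unified_model` with element `levels`.
#' @examples
#' m <- unified_model(G = c(0.0091, 0.09, 86), Rg = c(25.5, 110, 590),
#'                    B = c(0, 1.7e-6, 43.3e-10), df = c(4, 2.34, 4))
#' unified_intensity(0.01, m)
#' @export
unified_model <- function(G, Rg, B = 0, df = 4, k_sc = 1.06, levels = NULL) {
  if (is.null(levels)) {
    n <- length(Rg)
    stopifnot(length(G) == n)
    B <- rep_len(B, n); df <- rep_len(df, n); k_sc <- rep_len(k_sc, n)
    levels <- lapply(seq_len(n), function(i)
      unified_level(G[i], Rg[i], B[i], df[i], k_sc[i]))
  }
  stopifnot(length(levels) >= 1, all(vapply(levels, inherits, TRUE, "unified_level")))
  rg <- vapply(levels, `[[`, 0, "Rg")
  if (is.unsorted(rg, strictly = TRUE))
    stop("level Rg values must be strictly increasing (smallest level first)")
  for (i in seq_along(levels))
    levels[[i]]$Rg_cutoff <- if (i == 1) 0 else rg[i - 1]
  structure(list(levels = levels), class = "unified_model")
}

#' Number of levels of a Unified model
#' @param model a [unified_model()].
#' @export
n_levels <- function(model) length(model$levels)

#' Total intensity of a Unified model
#'
#' Sum of [level_intensity()] over all levels of the stack.
#'
#' @param q scattering vector grid, 1/Angstrom.
#' @param model a [unified_model()].
#' @return Intensity in 1/cm.
#' @export
unified_intensity <- function(q, model) {
  stopifnot(inherits(model, "unified_model"))
  Reduce(`+`, lapply(model$levels, function(l) level_intensity(q, l)))
}

#' @export
coef.unified_model <- function(object, ...) {
  n <- n_levels(object)
  out <- numeric(0)
  for (i in seq_len(n)) {
    l <- object$levels[[i]]
    v <- c(l$G, l$Rg, l$B, l$df)
    names(v) <- paste0(c("G", "Rg", "B", "df"), i)
    out <- c(out, v)
  }
  out
}

#' @export
print.unified_model <- function(x, ...) {
  cat(sprintf("unified scattering model, %d level(s) (smallest first)\n",
              n_levels(x)))
  for (i in seq_len(n_levels(x))) {
    l <- x$levels[[i]]
    cat(sprintf("  level %d: G = %.4g 1/cm, Rg = %.4g A, B = %.4g, df = %.3g\n",
                i, l$G, l$Rg, l$B, l$df))
  }
  invisible(x)
}

#' Write Unified model parameters as structured text
#'
#' One `level` block per structural level (smallest first) of `key value`
#' pairs, `#` comments allowed; readable back with [read_unified_params()].
#'
#' @param model a [unified_model()].
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
write_unified_params <- function(model, path) {
  stopifnot(inherits(model, "unified_model"))
  con <- file(path, "wt")
  on.exit(close(con))
  writeLines("# unified scattering model parameters (smallest level first)", con)
  writeLines("# G [1/cm], Rg [Angstrom], B [1/cm Angstrom^-df], df, k_sc", con)
  for (i in seq_len(n_levels(model))) {
    l <- model$levels[[i]]
    writeLines(sprintf("level %d", i), con)
    writeLines(sprintf("  %s %.17g", c("G", "Rg", "B", "df", "k_sc"),
                       c(l$G, l$Rg, l$B, l$df, l$k_sc)), con)
  }
  invisible(path)
}

#' Read Unified model parameters from structured text
#'
#' @param path a file written by [write_unified_params()] (or hand-edited in
#'   the same `level N` / `key value` layout).
#' @return A [unified_model()].
#' @export
read_unified_params <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !grepl("^#", lines)]
  levels <- list()
  cur <- NULL
  flush <- function(cur, levels) {
    if (is.null(cur)) return(levels)
    c(levels, list(unified_level(G = cur[["G"]], Rg = cur[["Rg"]],
                                 B = cur[["B"]], df = cur[["df"]],
                                 k_sc = if ("k_sc" %in% names(cur)) cur[["k_sc"]] else 1.06)))
  }
  for (ln in lines) {
    if (grepl("^level\\b", ln)) {
      levels <- flush(cur, levels)
      cur <- c(B = 0, df = 4)
    } else {
      kv <- strsplit(sub("=", " ", ln), "\\s+")[[1]]
      if (length(kv) < 2) stop("cannot parse parameter line: ", ln)
      cur[kv[1]] <- as.numeric(kv[2])
    }
  }
  levels <- flush(cur, levels)
  if (length(levels) == 0) stop("no level blocks found in ", path)
  unified_model(levels = levels)
}

#' Guinier analysis of the low-q regime
#'
#' Iteratively fits `ln I = ln G - q^2 Rg^2 / 3` over the window
#' `q Rg <= qrg_max`, re-selecting the window from the current `Rg` estimate
#' until it stabilises. Only points with positive intensity enter the
#' regression.
#'
#' @param profile a [scattering_profile()], or a numeric q vector.
#' @param I intensities when `profile` is a plain q vector.
#' @param qrg_max upper edge of the Guinier window in units of `q Rg`
#'   (conventionally 1-1.3).
#' @return A list with elements `G`, `Rg` and `n` (points used).
#' @export
guinier_fit <- function(profile, I = NULL, qrg_max = 1.3) {
  if (inherits(profile, "scattering_profile")) {
    q <- profile$q; I <- profile$I
  } else {
    q <- profile
  }
  ok <- I > 0
  q <- q[ok]; I <- I[ok]
  if (length(q) < 3) stop("need at least 3 positive-intensity points")
  use <- seq_len(max(3L, length(q) %/% 10L))
  Rg <- NA_real_
  for (iter in 1:20) {
    fit <- stats::lm(log(I[use]) ~ I(q[use]^2))
    slope <- coef(fit)[2]
    if (!is.finite(slope) || slope >= 0) break
    Rg_new <- sqrt(-3 * slope)
    use_new <- which(q <= qrg_max / Rg_new)
    if (length(use_new) < 3) use_new <- seq_len(3L)
    if (isTRUE(all.equal(use_new, use)) || (is.finite(Rg) && abs(Rg_new / Rg - 1) < 1e-10)) {
      Rg <- Rg_new; use <- use_new; break
    }
    Rg <- Rg_new; use <- use_new
  }
  fit <- stats::lm(log(I[use]) ~ I(q[use]^2))
  slope <- coef(fit)[2]
  if (!is.finite(slope) || slope >= 0)
    stop("no Guinier decay detected in the selected window")
  list(G = exp(coef(fit)[[1]]), Rg = sqrt(-3 * slope[[1]]), n = length(use))
}
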