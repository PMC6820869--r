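#' Degree of aggregation from Guinier prefactors
#'
#' Because the Guinier prefactor of a level is `n V^2 drho^2` and the
#' contrast is shared across levels, the ratio of an upper level's prefactor
#' to the one below it counts how many lower-level units make up an average
#' upper-level unit (e.g. monomers per aggregate), independently of absolute
#' intensity calibration.
#'
#' @param G_upper,G_lower Guinier prefactors, 1/cm (both positive).
#' @return Dimensionless aggregation number `G_upper / G_lower`.
#' @export
degree_of_aggregation <- function(G_upper, G_lower) {
  stopifnot(all(G_upper > 0), all(G_lower > 0))
  G_upper / G_lower
}

#' Volume ratio from radii of gyration
#'
#' Assumes volume scales as `Rg^3`; see [packing_fraction()] for the caveat
#' on anisometric particles.
#'
#' @param Rg_upper,Rg_lower radii of gyration, Angstrom (both positive).
#' @return `(Rg_upper / Rg_lower)^3`.
#' @export
volume_ratio <- function(Rg_upper, Rg_lower) {
  stopifnot(all(Rg_upper > 0), all(Rg_lower > 0))
  (Rg_upper / Rg_lower)^3
}

#' Packing fraction of subunits within a structure
#'
#' Aggregation number divided by volume ratio. Values above 1 are physically
#' impossible for isometric particles and are reported with a warning rather
#' than clamped: they diagnose spatially extended (rod- or platelet-like)
#' subunits whose volume grows slower than `Rg^3`.
#'
#' @param z aggregation number (positive).
#' @param volume_ratio volume ratio (positive).
#' @return Dimensionless packing fraction.
#' @export
packing_fraction <- function(z, volume_ratio) {
  stopifnot(all(z > 0), all(volume_ratio > 0))
  phi <- z / volume_ratio
  if (any(phi > 1))
    warning("packing fraction exceeds 1: subunits cannot be isometric ",
            "(rod- or platelet-like anisometry indicated)")
  phi
}

#' Fractal resistance scaling (Cates)
#'
#' A random walk on a mass fractal of dimension `df` traces a path of
#' dimension `df/2`, so the resistance of a fractal conductor scales as
#' `Omega(R) ~ R^(-df/2)`; lower fractal dimensions imply higher resistivity
#' contributions from the aggregate arrangement.
#'
#' @param R_ratio size ratio (positive).
#' @param df mass fractal dimension (positive).
#' @return Relative resistance `R_ratio^(-df/2)`.
#' @export
resistance_scaling <- function(R_ratio, df) {
  stopifnot(all(R_ratio > 0), all(df > 0))
  R_ratio^(-df / 2)
}

#' Hierarchy metrics of a 3-level Unified model
#'
#' Derives the quantities that summarise a monomer / aggregate / cluster
#' hierarchy from fitted Unified parameters: degrees of aggregation
#' (`z_a` monomers per aggregate, `z_c` aggregates per cluster, `z_total`
#' monomers per cluster, with `z_total = z_a * z_c` exactly), `Rg^3` volume
#' ratios, packing fractions at each pairing, and the Cates resistivity
#' exponent `df/2` of the intermediate fractal level. All metrics are ratios
#' and therefore invariant under uniform intensity recalibration. When
#' applied to a [unified_fit()], 1-sigma uncertainties are propagated from
#' the parameter covariance by the first-order delta method.
#'
#' @param x a 3-level [unified_fit()] or [unified_model()].
#' @param ... unused.
#' @return An object of class `hierarchy_metrics`: data frame with columns
#'   `value` and (for fits) `stderr`, rows `z_a`, `z_c`, `z_total`,
#'   `vr_aG`, `vr_cG`, `vr_ca`, `phi_agg`, `phi_cluster`,
#'   `phi_agg_in_cluster`, `resist_exponent`.
#' @examples
#' hierarchy_metrics(gox_reference_model(1))
#' @export
hierarchy_metrics <- function(x, ...) UseMethod("hierarchy_metrics")

.metric_values <- function(p) {
  # p: named vector G1..G3, Rg1..Rg3, df2
  z_a <- p[["G2"]] / p[["G1"]]
  z_c <- p[["G3"]] / p[["G2"]]
  z_total <- p[["G3"]] / p[["G1"]]
  vr_aG <- (p[["Rg2"]] / p[["Rg1"]])^3
  vr_cG <- (p[["Rg3"]] / p[["Rg1"]])^3
  vr_ca <- (p[["Rg3"]] / p[["Rg2"]])^3
  c(z_a = z_a, z_c = z_c, z_total = z_total,
    vr_aG = vr_aG, vr_cG = vr_cG, vr_ca = vr_ca,
    phi_agg = z_a / vr_aG, phi_cluster = z_total / vr_cG,
    phi_agg_in_cluster = z_c / vr_ca,
    resist_exponent = p[["df2"]] / 2)
}

.metrics_from_coef <- function(cf, vcv = NULL) {
  need <- c("G1", "G2", "G3", "Rg1", "Rg2", "Rg3", "df2")
  p <- cf[need]
  vals <- .metric_values(p)
  se <- rep(NA_real_, length(vals))
  if (!is.null(vcv)) {
    free <- intersect(need, colnames(vcv))
    Gm <- pracma::jacobian(function(th) {
      pp <- p; pp[free] <- th
      as.numeric(.metric_values(pp))
    }, p[free])
    se <- sqrt(pmax(diag(Gm %*% vcv[free, free, drop = FALSE] %*% t(Gm)), 0))
  }
  out <- data.frame(value = as.numeric(vals), stderr = se,
                    row.names = names(vals))
  phi <- vals[c("phi_agg", "phi_cluster", "phi_agg_in_cluster")]
  if (any(phi > 1))
    warning("packing fraction(s) above 1: ",
            paste(names(phi)[phi > 1], collapse = ", "),
            " -- subunits are anisometric (rod/platelet-like), Rg^3 ",
            "misrepresents their volume")
  structure(out, class = c("hierarchy_metrics", "data.frame"))
}

#' @rdname hierarchy_metrics
#' @export
hierarchy_metrics.unified_model <- function(x, ...) {
  if (n_levels(x) != 3) stop("hierarchy metrics require a 3-level model, got ",
                             n_levels(x), " level(s)")
  .metrics_from_coef(coef(x))
}

#' @rdname hierarchy_metrics
#' @export
hierarchy_metrics.unified_fit <- function(x, ...) {
  if (n_levels(x$model) != 3)
    stop("hierarchy metrics require a 3-level fit, got ",
         n_levels(x$model), " level(s)")
  .metrics_from_coef(coef(x), x$vcov)
}

#' @export
print.hierarchy_metrics <- function(x, ...) {
  cat("hierarchy metrics (monomer / aggregate / cluster)\n")
  disp <- data.frame(value = signif(x$value, 3),
                     stderr = signif(x$stderr, 2), row.names = rownames(x))
  if (all(is.na(disp$stderr))) disp$stderr <- NULL
  print(disp)
  cat("(displayed at 2-3 significant figures; full precision in $value)\n")
  invisible(x)
}
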