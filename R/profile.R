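#' One-dimensional scattering profile
#'
#' Container for an azimuthally averaged small-angle scattering curve:
#' scattering vector magnitudes `q` (1/Angstrom), differential scattering
#' cross-sections `I` (1/cm) and their 1-sigma uncertainties `sigma` (1/cm).
#' Rows with non-finite entries are dropped with a warning. `q` must end up
#' strictly increasing and positive; `sigma` must be positive. Negative
#' intensities are legitimate after background subtraction and are kept, but
#' their indices are recorded in the `"negative"` attribute.
#'
#' @param q numeric vector of scattering vector magnitudes, 1/Angstrom.
#' @param I numeric vector of intensities, 1/cm.
#' @param sigma numeric vector of 1-sigma intensity uncertainties, 1/cm.
#' @param label free-text description carried through file headers.
#' @param sort sort points by `q` (default). With `sort = FALSE` a
#'   non-monotone `q` is an error.
#' @return An object of class `scattering_profile`.
#' @examples
#' p <- scattering_profile(c(0.01, 0.02, 0.03), c(5, 4, 3), c(0.1, 0.1, 0.1))
#' p
#' @export
scattering_profile <- function(q, I, sigma, label = "", sort = TRUE) {
  q <- as.numeric(q); I <- as.numeric(I); sigma <- as.numeric(sigma)
  if (length(q) != length(I) || length(q) != length(sigma))
    stop("q, I and sigma must have equal length")
  ok <- is.finite(q) & is.finite(I) & is.finite(sigma)
  if (any(!ok)) {
    warning(sprintf("dropped %d row(s) with non-finite values", sum(!ok)))
    q <- q[ok]; I <- I[ok]; sigma <- sigma[ok]
  }
  if (length(q) == 0L) stop("no valid data points")
  if (sort) {
    o <- order(q)
    q <- q[o]; I <- I[o]; sigma <- sigma[o]
  } else if (is.unsorted(q, strictly = TRUE)) {
    stop("q must be strictly increasing (or use sort = TRUE)")
  }
  if (any(q <= 0)) stop("all q must be positive")
  if (anyDuplicated(q)) stop("duplicate q values")
  if (any(sigma <= 0)) stop("all sigma must be positive")
  out <- structure(list(q = q, I = I, sigma = sigma, label = as.character(label)[1]),
                   class = "scattering_profile")
  attr(out, "negative") <- which(I < 0)
  out
}

#' @export
print.scattering_profile <- function(x, ...) {
  cat(sprintf("scattering profile: %d points, q in [%.4g, %.4g] 1/Angstrom\n",
              length(x$q), min(x$q), max(x$q)))
  if (nzchar(x$label)) cat("  label:", x$label, "\n")
  nneg <- length(attr(x, "negative"))
  if (nneg) cat(sprintf("  %d negative intensity point(s) (flagged)\n", nneg))
  invisible(x)
}

#' @export
as.data.frame.scattering_profile <- function(x, ...) {
  data.frame(q = x$q, I = x$I, sigma = x$sigma)
}

#' @export
plot.scattering_profile <- function(x, ...) {
  args <- list(...)
  defaults <- list(x = x$q, y = abs(x$I), log = "xy",
                   xlab = "q [1/Angstrom]", ylab = "I(q) [1/cm]", pch = 16,
                   cex = 0.5, main = x$label)
  do.call(plot, utils::modifyList(defaults, args))
  invisible(x)
}

#' Read a 3-column ASCII scattering profile
#'
#' Reads the de facto small-angle scattering `.dat` convention: `#`-prefixed
#' header lines followed by at least three numeric columns `q`, `I`, `sigma`
#' (a fourth resolution column, if present, is read and ignored). Whitespace
#' and comma separated dialects are supported; `"auto"` detects commas.
#'
#' @param path file to read.
#' @param dialect `"auto"`, `"whitespace"` or `"csv"`.
#' @param sort passed to [scattering_profile()].
#' @return A [scattering_profile()].
#' @export
read_profile <- function(path, dialect = c("auto", "whitespace", "csv"),
                         sort = TRUE) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  header <- lines[grepl("^\\s*#", lines)]
  body <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(body) == 0L) stop("no data rows in ", path)
  if (dialect == "auto")
    dialect <- if (grepl(",", body[1])) "csv" else "whitespace"
  sep <- if (dialect == "csv") "," else ""
  tab <- utils::read.table(text = body, sep = sep, header = FALSE,
                           fill = TRUE, colClasses = "numeric",
                           comment.char = "")
  if (ncol(tab) < 3L)
    stop("missing sigma column: need at least 3 columns (q, I, sigma), found ",
         ncol(tab))
  label <- ""
  lab <- grep("^#\\s*label:", header, value = TRUE)
  if (length(lab)) label <- trimws(sub("^#\\s*label:", "", lab[1]))
  scattering_profile(tab[[1]], tab[[2]], tab[[3]], label = label, sort = sort)
}

#' Write a scattering profile as 3-column ASCII
#'
#' Writes `q I sigma` columns at full double precision under a `#` header
#' that records units, label and provenance, so that
#' `read_profile(write_profile(p))` reproduces `p` exactly.
#'
#' @param profile a [scattering_profile()].
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path) {
  stopifnot(inherits(profile, "scattering_profile"))
  if (length(profile$q) == 0L) stop("refusing to write an empty profile")
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c(
    sprintf("# label: %s", profile$label),
    "# columns: q [1/Angstrom]  I [1/cm]  sigma [1/cm]",
    sprintf("# written by sashier %s", as.character(utils::packageVersion("sashier")))
  ), con)
  writeLines(sprintf("%.17g %.17g %.17g", profile$q, profile$I, profile$sigma),
             con)
  invisible(path)
}

#' Restrict a profile to a q window
#'
#' Keeps points with `qmin <= q <= qmax`, preserving order and values.
#'
#' @param profile a [scattering_profile()].
#' @param qmin,qmax window bounds, 1/Angstrom.
#' @return A [scattering_profile()] on the sub-window.
#' @export
restrict_q <- function(profile, qmin = 0, qmax = Inf) {
  stopifnot(inherits(profile, "scattering_profile"))
  if (qmin >= qmax) stop("qmin must be < qmax")
  keep <- profile$q >= qmin & profile$q <= qmax
  if (!any(keep)) stop("no points left in [", qmin, ", ", qmax, "]")
  scattering_profile(profile$q[keep], profile$I[keep], profile$sigma[keep],
                     label = profile$label, sort = FALSE)
}
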