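#' Locate the concentration at peak kernel density
#'
#' Finds the mode of a Gaussian kernel density estimate of the
#' concentration distribution: the KDE (normal-reference/Scott-type
#' bandwidth, \code{stats::bw.nrd}) is evaluated on a regular grid spanning
#' the data range and the grid abscissa of the maximum is returned. This
#' concentration is the lower cutoff for tail fitting: only values above
#' the density peak are analysed.
#'
#' @param values at least 100 concentrations.
#' @param n_grid number of evaluation points (default 512).
#' @param bw bandwidth rule or value, passed to \code{stats::density}.
#' @return the concentration at the density maximum.
#' @export
kde_peak <- function(values, n_grid = 512L, bw = "nrd") {
  values <- values[is.finite(values)]
  if (length(values) < 100L)
    stop("need at least 100 values for a stable density peak", call. = FALSE)
  if (stats::sd(values) == 0)
    stop("constant data: kernel bandwidth is zero", call. = FALSE)
  d <- stats::density(values, bw = bw, n = n_grid,
                      from = min(values), to = max(values))
  d$x[which.max(d$y)]
}

#' Extract the above-peak concentration tail
#'
#' Retains values strictly greater than the density-peak cutoff and shifts
#' them to the origin, \eqn{y = x - x_{peak}}; the below-peak part of the
#' distribution is discarded. All candidate families are subsequently
#' fitted on \eqn{y > 0} with location fixed at zero.
#'
#' @param values concentrations.
#' @param x_peak the cutoff from \code{\link{kde_peak}}.
#' @return an object of class \code{"tail_cut"}: list with \code{x_peak},
#'   \code{tail_values} (shifted, all positive), \code{n_tail},
#'   \code{n_total}.
#' @export
extract_tail <- function(values, x_peak) {
  if (!is.finite(x_peak)) stop("'x_peak' must be finite", call. = FALSE)
  values <- values[is.finite(values)]
  y <- values[values > x_peak] - x_peak
  if (length(y) == 0L)
    stop("empty tail: no values above the density peak", call. = FALSE)
  structure(list(x_peak = x_peak, tail_values = y, n_tail = length(y),
                 n_total = length(values)),
            class = "tail_cut")
}

#' @export
print.tail_cut <- function(x, ...) {
  cat(sprintf("tail cut at x_peak = %.4g: %d of %d values retained\n",
              x$x_peak, x$n_tail, x$n_total))
  invisible(x)
}

#' Mean and standard deviation for the exponentiality check
#'
#' For an exponential distribution mean and standard deviation coincide
#' (both equal \eqn{1/\lambda}), so plotting sample sd against sample mean
#' across sites tests the exponential hypothesis: points off the diagonal
#' indicate non-exponential statistics (heavy tails inflate sd/mean above
#' one).
#'
#' @param values raw (QC-passed, unshifted) concentrations, at least 2.
#' @return named numeric vector \code{c(mean, sd)}.
#' @export
exponentiality_check <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) < 2L) stop("need at least 2 values", call. = FALSE)
  c(mean = mean(values), sd = stats::sd(values))
}

#' Fit all candidate tail distributions to one site
#'
#' The per-site fitting procedure: run quality control, locate the kernel
#' density peak, extract the strictly-above-peak tail shifted to the
#' origin, fit all five candidate families by maximum likelihood on the
#' shifted tail, and select the family with the highest log-likelihood.
#' The reported \code{q} and \code{lambda} are the q-exponential estimates
#' on the shifted variable; \code{mean} and \code{sd} are the raw-series
#' moments for the exponentiality check.
#'
#' Failures at any stage (QC rejection, empty tail, non-convergent fit)
#' produce a flagged record (\code{ok = FALSE} with the failure reason),
#' never a silent drop.
#'
#' @param series a \code{\link{site_series}}.
#' @param config a \code{\link{pipeline_config}}.
#' @param qc set to \code{FALSE} to skip quality control (e.g. for already
#'   filtered data).
#' @return an object of class \code{"site_fit"}: list with \code{site},
#'   \code{pollutant}, \code{ok}, \code{error}, \code{tailcut},
#'   \code{fits} (named list of \code{candidate_fit}), \code{best_family},
#'   \code{q}, \code{lambda}, \code{mean}, \code{sd}.
#' @export
fit_site <- function(series, config = pipeline_config(), qc = TRUE) {
  fail <- function(msg) structure(
    list(site = series$site, pollutant = series$pollutant, ok = FALSE,
         error = msg, tailcut = NULL, fits = NULL,
         best_family = NA_character_, q = NA_real_, lambda = NA_real_,
         mean = NA_real_, sd = NA_real_),
    class = "site_fit")

  if (qc) {
    rep <- run_qc(series, config)
    if (!rep$passed)
      return(fail(paste("QC failed:", paste(rep$reasons, collapse = ", "))))
    series <- rep$series
  } else if (!is.na(series$lod)) {
    series <- substitute_lod(series)
  }
  v <- series$value[!is.na(series$value)]

  out <- tryCatch({
    xp <- kde_peak(v, n_grid = config$kde_grid, bw = config$kde_bw)
    tc <- extract_tail(v, xp)
    fams <- c("exponential", "gamma", "weibull", "lognormal", "qexponential")
    fits <- lapply(fams, function(f) fit_tail_family(tc$tail_values, f))
    names(fits) <- fams
    cmp <- compare_models(fits)
    ms <- exponentiality_check(v)
    structure(list(site = series$site, pollutant = series$pollutant,
                   ok = TRUE, error = NA_character_, tailcut = tc,
                   fits = fits, best_family = cmp$best,
                   q = fits$qexponential$params[["q"]],
                   lambda = fits$qexponential$params[["lambda"]],
                   mean = ms[["mean"]], sd = ms[["sd"]]),
              class = "site_fit")
  }, error = function(e) fail(conditionMessage(e)))
  out
}

#' @export
print.site_fit <- function(x, digits = 4, ...) {
  if (!x$ok) {
    cat(sprintf("site fit %s / %s: FAILED (%s)\n", x$site, x$pollutant,
                x$error))
    return(invisible(x))
  }
  cat(sprintf("site fit %s / %s\n", x$site, x$pollutant))
  cat(sprintf("  tail cutoff x_peak = %.*g (%d tail points)\n", digits,
              x$tailcut$x_peak, x$tailcut$n_tail))
  cat(sprintf("  q = %.*f, lambda = %.*g; best family: %s\n", digits, x$q,
              digits, x$lambda, x$best_family))
  cat(sprintf("  raw mean = %.*g, sd = %.*g\n", digits, x$mean, digits, x$sd))
  invisible(x)
}
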