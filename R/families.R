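#' Fit a candidate tail distribution by maximum likelihood
#'
#' Fits one of the five candidate families used to describe the
#' above-the-peak concentration tail: exponential, gamma, Weibull,
#' log-normal or q-exponential. All families are fitted on the shifted tail
#' variable \eqn{y = x - x_{peak} > 0} with location fixed at zero, so the
#' log-likelihoods are directly comparable.
#'
#' The exponential MLE is closed-form (\eqn{\hat\lambda = 1/\bar y}), as is
#' the log-normal (moments of \eqn{\log y}); gamma and Weibull use
#' \code{MASS::fitdistr}; the q-exponential uses \code{\link{fit_qexp}}.
#'
#' @param y positive tail concentrations (at least 50 points).
#' @param family one of \code{"exponential"}, \code{"gamma"},
#'   \code{"weibull"}, \code{"lognormal"}, \code{"qexponential"}.
#' @return an object of class \code{"candidate_fit"}: list with
#'   \code{family}, \code{params} (named), \code{loglik}, \code{npar},
#'   \code{n}.
#' @examples
#' set.seed(7); y <- rexp(1000, rate = 0.5)
#' fit_tail_family(y, "exponential")
#' @seealso \code{\link{compare_models}}
#' @export
fit_tail_family <- function(y,
                            family = c("exponential", "gamma", "weibull",
                                       "lognormal", "qexponential")) {
  family <- match.arg(family)
  y <- y[is.finite(y)]
  n <- length(y)
  if (n < 50L) stop("need at least 50 positive data points", call. = FALSE)
  if (any(y <= 0)) stop("all data must be strictly positive", call. = FALSE)

  res <- switch(family,
    exponential = {
      rate <- 1 / mean(y)
      list(params = c(rate = rate),
           loglik = sum(stats::dexp(y, rate, log = TRUE)), npar = 1L)
    },
    gamma = {
      f <- try(MASS::fitdistr(y, "gamma", lower = c(1e-10, 1e-10)),
               silent = TRUE)
      if (inherits(f, "try-error")) {
        # direct optimization on log parameters from a moment start
        m <- mean(y); v <- stats::var(y)
        p0 <- log(c(shape = m^2 / v, rate = m / v))
        o <- stats::optim(p0, function(p)
          -sum(stats::dgamma(y, exp(p[1]), exp(p[2]), log = TRUE)))
        list(params = c(shape = exp(o$par[1]), rate = exp(o$par[2])),
             loglik = -o$value, npar = 2L)
      } else {
        list(params = f$estimate, loglik = as.numeric(stats::logLik(f)),
             npar = 2L)
      }
    },
    weibull = {
      f <- MASS::fitdistr(y, "weibull", lower = c(1e-10, 1e-10))
      list(params = f$estimate, loglik = as.numeric(stats::logLik(f)),
           npar = 2L)
    },
    lognormal = {
      ly <- log(y)
      mu <- mean(ly)
      sdl <- sqrt(mean((ly - mu)^2))  # ML variant, divisor n
      if (sdl == 0) stop("degenerate data for log-normal fit", call. = FALSE)
      list(params = c(meanlog = mu, sdlog = sdl),
           loglik = sum(stats::dlnorm(y, mu, sdl, log = TRUE)), npar = 2L)
    },
    qexponential = {
      f <- fit_qexp(y)
      list(params = coef(f), loglik = f$loglik, npar = 2L)
    })

  structure(list(family = family, params = res$params, loglik = res$loglik,
                 npar = res$npar, n = n),
            class = "candidate_fit")
}

#' @export
print.candidate_fit <- function(x, digits = 4, ...) {
  cat(sprintf("%s fit (n = %d): log-likelihood %.*f\n",
              x$family, x$n, digits, x$loglik))
  print(signif(x$params, digits))
  invisible(x)
}

#' Rank candidate tail fits by log-likelihood
#'
#' Sorts candidate-family fits on the same data by attained log-likelihood,
#' highest first; the distribution with the highest log-likelihood is the
#' best fit. Exact ties are broken toward the family with fewer parameters.
#'
#' @param fits a list of \code{\link{fit_tail_family}} results, all on the
#'   same sample (same \code{n}).
#' @return an object of class \code{"model_comparison"}: list with
#'   \code{ranking} (data frame family/loglik/npar, sorted) and
#'   \code{best} (family name).
#' @export
compare_models <- function(fits) {
  if (!is.list(fits) || length(fits) < 2L)
    stop("need at least two fits to compare", call. = FALSE)
  if (!all(vapply(fits, inherits, logical(1), "candidate_fit")))
    stop("all elements must be 'candidate_fit' objects", call. = FALSE)
  ns <- vapply(fits, `[[`, numeric(1), "n")
  if (length(unique(ns)) != 1L)
    stop("fits were computed on different sample sizes; log-likelihoods ",
         "are not comparable", call. = FALSE)
  rk <- data.frame(
    family = vapply(fits, `[[`, character(1), "family"),
    loglik = vapply(fits, `[[`, numeric(1), "loglik"),
    npar = vapply(fits, `[[`, integer(1), "npar"),
    stringsAsFactors = FALSE)
  rk <- rk[order(-rk$loglik, rk$npar), , drop = FALSE]
  rownames(rk) <- NULL
  structure(list(ranking = rk, best = rk$family[1], n = ns[1]),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, digits = 4, ...) {
  cat(sprintf("Model comparison on n = %d tail points (best: %s)\n",
              x$n, x$best))
  print(transform(x$ranking, loglik = round(loglik, digits)))
  invisible(x)
}
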