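#' The q-exponential distribution
#'
#' Density, distribution function, quantile function and random generation
#' for the Tsallis q-exponential distribution with entropic index \code{q}
#' and width parameter \code{lambda},
#' \deqn{f_{q,\lambda}(x) = (2-q)\,\lambda\,[1 - \lambda(1-q)x]^{1/(1-q)},
#'   \quad 1 - \lambda(1-q)x \ge 0,\ x > 0.}
#'
#' For \eqn{q = 1} the distribution reduces to the exponential with rate
#' \eqn{\lambda}. For \eqn{q > 1} the density decays asymptotically as a
#' power law with exponent \eqn{-1/(q-1)}; for \eqn{q < 1} it has finite
#' support \eqn{[0, 1/(\lambda(1-q))]} and is exactly zero beyond the
#' endpoint. Normalizability requires \eqn{0 < q < 2} and \eqn{\lambda > 0}.
#'
#' In the superstatistical picture the q-exponential arises as the marginal
#' of exponentially distributed concentrations whose rate \eqn{\lambda}
#' fluctuates slowly; see \code{\link{marginal_qexp}} and
#' \code{\link{superstat_q}}.
#'
#' @param x vector of quantiles (concentrations, e.g. in ug/m3).
#' @param p vector of probabilities in \eqn{[0, 1)}.
#' @param n number of observations.
#' @param q entropic index, \eqn{0 < q < 2}.
#' @param lambda width parameter, \eqn{\lambda > 0}, units 1/(ug/m3).
#' @param log,log.p logical; if TRUE, probabilities/densities are returned
#'   on the log scale.
#' @param lower.tail logical; if TRUE (default), probabilities are
#'   \eqn{P(X \le x)}.
#'
#' @return \code{dqexp} gives the density, \code{pqexp} the distribution
#'   function, \code{qqexp} the quantile function and \code{rqexp} generates
#'   random deviates (by inverse-transform sampling).
#'
#' @examples
#' dqexp(1, q = 1, lambda = 1)           # exp(-1)
#' pqexp(2, q = 0.5, lambda = 1)         # 1: support endpoint
#' qqexp(0.5, q = 1, lambda = 2)         # log(2)/2, exponential median
#' set.seed(1); x <- rqexp(1000, q = 1.3, lambda = 0.1)
#'
#' @name qexp_dist
NULL

check_qexp_params <- function(q, lambda) {
  if (!is.numeric(q) || length(q) != 1L || !is.finite(q) || q <= 0 || q >= 2)
    stop("'q' must be a single value in (0, 2)", call. = FALSE)
  if (!is.numeric(lambda) || length(lambda) != 1L || !is.finite(lambda) ||
      lambda <= 0)
    stop("'lambda' must be a single positive value", call. = FALSE)
  invisible(TRUE)
}

#' @rdname qexp_dist
#' @export
dqexp <- function(x, q, lambda, log = FALSE) {
  check_qexp_params(q, lambda)
  if (q == 1) {
    d <- stats::dexp(x, rate = lambda, log = log)
    d[x <= 0] <- if (log) -Inf else 0
    return(d)
  }
  t <- 1 - lambda * (1 - q) * x
  logf <- rep(-Inf, length(x))
  ok <- is.finite(x) & x > 0 & t > 0
  logf[ok] <- log((2 - q) * lambda) + log(t[ok]) / (1 - q)
  # q < 1 support endpoint: density 0 there only if exponent negative (never
  # for q < 1, where 1/(1-q) > 0, so t == 0 gives density 0 anyway)
  if (log) logf else exp(logf)
}

#' @rdname qexp_dist
#' @export
pqexp <- function(x, q, lambda, lower.tail = TRUE, log.p = FALSE) {
  check_qexp_params(q, lambda)
  if (q == 1) {
    p <- stats::pexp(pmax(x, 0), rate = lambda)
  } else {
    t <- pmax(1 - lambda * (1 - q) * x, 0)
    p <- 1 - t^((2 - q) / (1 - q))
    p[x <= 0] <- 0
    p <- pmin(pmax(p, 0), 1)
  }
  if (!lower.tail) p <- 1 - p
  if (log.p) log(p) else p
}

#' @rdname qexp_dist
#' @export
qqexp <- function(p, q, lambda) {
  check_qexp_params(q, lambda)
  if (any(!is.finite(p) | p < 0 | p >= 1))
    stop("'p' must lie in [0, 1)", call. = FALSE)
  if (q == 1) return(stats::qexp(p, rate = lambda))
  (1 - (1 - p)^((1 - q) / (2 - q))) / (lambda * (1 - q))
}

#' @rdname qexp_dist
#' @export
rqexp <- function(n, q, lambda) {
  check_qexp_params(q, lambda)
  qqexp(stats::runif(n), q, lambda)
}

#' Mean of the q-exponential distribution
#'
#' The mean \eqn{1/(\lambda(3-2q))}, finite only for \eqn{q < 3/2}.
#'
#' @inheritParams qexp_dist
#' @return the mean concentration.
#' @examples
#' qexp_mean(q = 1, lambda = 2)     # 0.5, exponential mean
#' qexp_mean(q = 1.25, lambda = 1)  # 2
#' @export
qexp_mean <- function(q, lambda) {
  check_qexp_params(q, lambda)
  if (q >= 1.5)
    stop("mean of the q-exponential diverges for q >= 1.5", call. = FALSE)
  1 / (lambda * (3 - 2 * q))
}

# squared coefficient of variation, finite for q < 4/3:
# E[X^2] = 2 / (lambda^2 (3-2q)(4-3q))  =>  CV^2 = (2-q)/(4-3q)
qexp_cv2 <- function(q) (2 - q) / (4 - 3 * q)

#' Log-likelihood of a q-exponential sample
#'
#' Sum of log densities; \code{-Inf} if any point falls outside the support
#' (for \eqn{q < 1} the support is bounded above by \eqn{1/(\lambda(1-q))}).
#'
#' @param x positive concentrations.
#' @inheritParams qexp_dist
#' @return the log-likelihood, possibly \code{-Inf}.
#' @export
qexp_loglik <- function(x, q, lambda) {
  if (length(x) == 0L) stop("empty data", call. = FALSE)
  sum(dqexp(x, q, lambda, log = TRUE))
}

#' Superstatistical entropic index from rate samples
#'
#' The entropic index implied by fluctuations of the local exponential rate
#' \eqn{\lambda}: \eqn{q = \langle\lambda^2\rangle / \langle\lambda\rangle^2}.
#' Always \eqn{\ge 1} (Cauchy-Schwarz), with equality iff \eqn{\lambda} is
#' constant. Note for a Gamma(shape a) rate this gives \eqn{1 + 1/a}, which
#' differs from the exact marginal exponent \eqn{(a+2)/(a+1)} of
#' \code{\link{marginal_qexp}}: the first describes the rate fluctuations,
#' the second the normalized mixture density actually fitted to data.
#'
#' @param lambda_samples positive rate samples.
#' @return the entropic index, a value \eqn{\ge 1}.
#' @examples
#' superstat_q(c(1, 3))  # 1.25
#' @export
superstat_q <- function(lambda_samples) {
  if (length(lambda_samples) < 1L) stop("need at least one sample", call. = FALSE)
  if (any(!is.finite(lambda_samples) | lambda_samples <= 0))
    stop("all rate samples must be positive and finite", call. = FALSE)
  mean(lambda_samples^2) / mean(lambda_samples)^2
}
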