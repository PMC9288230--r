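#' Maximum-likelihood fit of a q-exponential distribution
#'
#' Estimates the entropic index \eqn{q} and width parameter \eqn{\lambda}
#' of the q-exponential by numerical maximization of the log-likelihood
#' over \eqn{0 < q < 2}, \eqn{\lambda > 0}. Both the heavy-tailed
#' (\eqn{q > 1}) and compact-support (\eqn{q < 1}) regimes are reachable;
#' for \eqn{q < 1} a data point beyond the candidate support
#' \eqn{[0, 1/(\lambda(1-q))]} makes the likelihood exactly zero (hard
#' rejection, not a penalty).
#'
#' Starting values come from the method of moments: the sample squared
#' coefficient of variation is mapped through the q-exponential identity
#' \eqn{CV^2 = (2-q)/(4-3q)} to \eqn{q_0 = (2 - 4CV^2)/(1 - 3CV^2)},
#' clipped to \eqn{[0.7, 1.8]}, and \eqn{\lambda_0 = 1/((3-2q_0)\,\bar x)}
#' (with \eqn{q_0} capped at 1.45 inside this formula so \eqn{\lambda_0}
#' stays positive). Three Nelder-Mead starts (\eqn{q_0}, \eqn{q_0 \pm 0.2})
#' on \eqn{(q, \log\lambda)} guard against the optimizer being trapped at
#' the \eqn{q = 1} regime boundary; the best attained log-likelihood wins.
#'
#' @param x positive concentrations; at least 50 points, not all identical.
#' @param reltol relative convergence tolerance on the log-likelihood.
#' @param maxit maximum optimizer iterations per start.
#'
#' @return an object of class \code{"qexp_fit"}: a list with components
#'   \code{q}, \code{lambda}, \code{loglik}, \code{n}, \code{convergence}
#'   (0 = converged for the winning start), \code{start} (the winning start
#'   values) and \code{data}. Methods: \code{print}, \code{summary},
#'   \code{coef}, \code{logLik}, \code{vcov}, \code{plot}, \code{simulate}.
#'
#' @examples
#' set.seed(42)
#' x <- rqexp(5000, q = 1.3, lambda = 0.1)
#' fit <- fit_qexp(x)
#' coef(fit)
#' logLik(fit)
#' @export
fit_qexp <- function(x, reltol = 1e-8, maxit = 500) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 50L)
    stop("need at least 50 finite data points to fit", call. = FALSE)
  if (any(x <= 0))
    stop("all data must be strictly positive", call. = FALSE)
  if (max(x) == min(x))
    stop("degenerate data: all values identical", call. = FALSE)

  m <- mean(x)
  cv2 <- stats::var(x) / m^2
  q0 <- (2 - 4 * cv2) / (1 - 3 * cv2)
  if (!is.finite(q0)) q0 <- 1
  q0 <- min(max(q0, 0.7), 1.8)
  lam0 <- 1 / ((3 - 2 * min(q0, 1.45)) * m)

  negll <- function(par) {
    qq <- par[1]; lam <- exp(par[2])
    if (qq <= 1e-3 || qq >= 2 - 1e-6 || !is.finite(lam) || lam <= 0)
      return(1e300)
    ll <- qexp_loglik(x, qq, lam)
    if (!is.finite(ll)) return(1e300)  # support violation: hard rejection
    -ll
  }

  starts <- unique(pmin(pmax(c(q0, q0 - 0.2, q0 + 0.2), 0.05), 1.95))
  best <- NULL
  for (qs in starts) {
    fit <- stats::optim(c(qs, log(lam0)), negll, method = "Nelder-Mead",
                        control = list(reltol = reltol, maxit = maxit))
    if (is.null(best) || fit$value < best$value) {
      best <- fit
      best_start <- c(q = qs, lambda = lam0)
    }
  }
  if (best$value >= 1e300)
    stop("q-exponential fit failed: no feasible parameters found",
         call. = FALSE)
  if (best$convergence != 0)
    warning("q-exponential fit did not converge within ", maxit,
            " iterations (code ", best$convergence, ")", call. = FALSE)

  structure(list(q = best$par[1], lambda = exp(best$par[2]),
                 loglik = -best$value, n = n,
                 convergence = best$convergence, start = best_start,
                 data = x, call = match.call()),
            class = "qexp_fit")
}

#' @export
print.qexp_fit <- function(x, digits = 4, ...) {
  cat("q-exponential maximum-likelihood fit\n")
  cat(sprintf("  n = %d, log-likelihood = %.*f\n", x$n, digits, x$loglik))
  cat(sprintf("  q      = %.*f\n", digits, x$q))
  cat(sprintf("  lambda = %.*g\n", digits, x$lambda))
  invisible(x)
}

#' @export
coef.qexp_fit <- function(object, ...) {
  c(q = object$q, lambda = object$lambda)
}

#' @export
logLik.qexp_fit <- function(object, ...) {
  structure(object$loglik, df = 2L, nobs = object$n, class = "logLik")
}

#' @export
vcov.qexp_fit <- function(object, ...) {
  h <- try(stats::optimHess(c(object$q, object$lambda), function(par) {
    -qexp_loglik(object$data, par[1], par[2])
  }), silent = TRUE)
  if (inherits(h, "try-error"))
    return(matrix(NA_real_, 2, 2,
                  dimnames = list(c("q", "lambda"), c("q", "lambda"))))
  v <- solve(h)
  dimnames(v) <- list(c("q", "lambda"), c("q", "lambda"))
  v
}

#' @export
summary.qexp_fit <- function(object, ...) {
  v <- vcov(object)
  se <- sqrt(pmax(diag(v), 0))
  out <- list(fit = object, se = se,
              tail_exponent = if (object$q > 1) -1 / (object$q - 1) else NA_real_,
              support_end = if (object$q < 1)
                1 / (object$lambda * (1 - object$q)) else Inf,
              mean = if (object$q < 1.5)
                qexp_mean(object$q, object$lambda) else NA_real_)
  class(out) <- "summary.qexp_fit"
  out
}

#' @export
print.summary.qexp_fit <- function(x, digits = 4, ...) {
  print(x$fit, digits = digits)
  cat(sprintf("  std. errors: q %.*g, lambda %.*g\n",
              digits, x$se[1], digits, x$se[2]))
  if (!is.na(x$tail_exponent))
    cat(sprintf("  power-law tail exponent -1/(q-1) = %.*f\n",
                digits, x$tail_exponent))
  if (is.finite(x$support_end))
    cat(sprintf("  finite support endpoint 1/(lambda(1-q)) = %.*g\n",
                digits, x$support_end))
  if (!is.na(x$mean))
    cat(sprintf("  mean 1/(lambda(3-2q)) = %.*g\n", digits, x$mean))
  invisible(x)
}

#' @export
simulate.qexp_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  rqexp(nsim, object$q, object$lambda)
}

#' @export
plot.qexp_fit <- function(x, breaks = 50, log = "y", ...) {
  h <- graphics::hist(x$data, breaks = breaks, plot = FALSE)
  keep <- h$density > 0
  graphics::plot(h$mids[keep], h$density[keep], log = log, pch = 16,
                 cex = 0.6, xlab = "concentration", ylab = "density", ...)
  xs <- seq(min(x$data), max(x$data), length.out = 400)
  ys <- dqexp(xs, x$q, x$lambda)
  graphics::lines(xs[ys > 0], ys[ys > 0], col = 2, lwd = 2)
  invisible(x)
}
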