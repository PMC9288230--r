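# independent quadrature oracle for the q-exponential CDF; piecewise over
# a log-spaced grid so very heavy tails (q near 2) integrate stably
qexp_cdf_quad <- function(x, q, lambda) {
  vapply(x, function(xx) {
    if (xx <= 0) return(0)
    up <- if (q < 1) min(xx, 1 / (lambda * (1 - q))) else xx
    breaks <- sort(c(0, 10^seq(-3, 15) / lambda, up))
    breaks <- breaks[breaks <= up]
    # drop degenerate pieces (width negligible relative to the local
    # scale), always keeping the upper limit itself
    breaks <- breaks[c(diff(breaks) > 1e-12 * breaks[-1], TRUE)]
    sum(vapply(seq_len(length(breaks) - 1), function(i) {
      piece <- function(rt, at) stats::integrate(
        function(t) dqexp(t, q, lambda), breaks[i], breaks[i + 1],
        rel.tol = rt, abs.tol = at)$value
      tryCatch(piece(1e-10, 1e-12), error = function(e) piece(1e-9, 1e-11))
    }, numeric(1)))
  }, numeric(1))
}

# numerically integrated Gamma-rate mixture density (superstat marginal)
mixture_density_quad <- function(x, a, theta) {
  vapply(x, function(xx) {
    stats::integrate(function(l) stats::dgamma(l, shape = a, scale = theta) *
                       l * exp(-l * xx),
                     0, Inf, rel.tol = 1e-13)$value
  }, numeric(1))
}

# hourly series with arbitrary values and optional metadata
make_series <- function(values, site = "s1", pollutant = "no2",
                        lod = NA_real_, ...) {
  site_series(site, pollutant, time = seq_along(values), values,
              lod = lod, ...)
}

# distinct-valued series of length n that passes every QC filter
clean_series <- function(n, seed = 1, lod = NA_real_) {
  set.seed(seed)
  make_series(rexp(n, rate = 0.05) + 1, lod = lod)
}
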