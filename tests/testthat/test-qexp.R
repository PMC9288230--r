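test_that("density matches closed forms at the exponential limit and support edges", {
  # f(0+) = (2-q)*lambda
  expect_equal(dqexp(1e-12, q = 1, lambda = 2), 2, tolerance = 1e-9)
  expect_equal(dqexp(1, q = 1, lambda = 1), exp(-1), tolerance = 1e-12)
  # finite support for q < 1: endpoint 1/(lambda(1-q)) = 2
  expect_identical(dqexp(2.5, q = 0.5, lambda = 1), 0)
  expect_identical(dqexp(-1, q = 1.2, lambda = 1), 0)
  expect_identical(dqexp(0, q = 1.2, lambda = 1), 0)
  # power-law tail ratio f(2x)/f(x) -> 2^{-1/(q-1)} for q = 1.5
  for (x in c(1e3, 1e4)) {
    expect_equal(dqexp(2 * x, 1.5, 1) / dqexp(x, 1.5, 1), 2^-2,
                 tolerance = 1e-2)
  }
})

test_that("invalid parameters are rejected across the distribution functions", {
  expect_error(dqexp(1, q = 0, lambda = 1), "q")
  expect_error(dqexp(1, q = 2, lambda = 1), "q")
  expect_error(pqexp(1, q = 1, lambda = -1), "lambda")
  expect_error(qqexp(0.5, q = 2.4, lambda = 1), "q")
  expect_error(qqexp(1, q = 1.2, lambda = 1), "\\[0, 1\\)")
  expect_error(qqexp(-0.1, q = 1.2, lambda = 1), "\\[0, 1\\)")
})

test_that("distribution function agrees with the quadrature oracle and closed forms", {
  expect_equal(pqexp(1, 1, 1), 1 - exp(-1), tolerance = 1e-12)
  expect_identical(pqexp(2, 0.5, 1), 1)  # total mass on finite support
  grid <- expand.grid(q = c(0.5, 0.9, 1, 1.3, 1.7),
                      lambda = c(0.05, 1, 20),
                      x = c(0.1, 0.5, 2, 10))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    expect_equal(pqexp(g$x, g$q, g$lambda),
                 qexp_cdf_quad(g$x, g$q, g$lambda), tolerance = 1e-8)
  }
})

test_that("quantile function is the exact inverse of the distribution function", {
  expect_identical(qqexp(0, 1.3, 2), 0)
  expect_equal(qqexp(0.5, 1, 2), log(2) / 2, tolerance = 1e-12)
  ps <- seq(0, 0.999, by = 0.037)
  for (par in list(c(0.6, 3), c(1, 1), c(1.4, 0.1))) {
    expect_equal(pqexp(qqexp(ps, par[1], par[2]), par[1], par[2]), ps,
                 tolerance = 1e-10)
  }
})

test_that("density is normalized over its support on a parameter grid", {
  for (q in c(0.5, 0.8, 1.0, 1.2, 1.5, 1.9)) {
    for (lambda in c(0.01, 1, 100)) {
      up <- if (q < 1) 1 / (lambda * (1 - q)) else Inf
      mass <- integrate(function(x) dqexp(x, q, lambda), 0, up,
                        rel.tol = 1e-12)$value
      expect_equal(mass, 1, tolerance = 1e-8)
    }
  }
})

test_that("density is continuous in q at the exponential point", {
  xs <- seq(1e-3, 50, length.out = 2000)
  for (q in c(1 - 1e-4, 1 + 1e-4)) {
    expect_lt(max(abs(dqexp(xs, q, 1) - dexp(xs, 1))), 1e-3)
  }
})

test_that("log-density is asymptotically linear in log x with slope -1/(q-1)", {
  for (q in c(1.2, 1.5, 1.8)) {
    xs <- 10^seq(3, 6, length.out = 50)
    slope <- coef(lm(log(dqexp(xs, q, 1)) ~ log(xs)))[[2]]
    expect_equal(slope, -1 / (q - 1), tolerance = 0.01)
  }
})

test_that("sampling is reproducible and distributed as the closed-form CDF", {
  set.seed(99); a <- rqexp(1000, 1.2, 1)
  set.seed(99); b <- rqexp(1000, 1.2, 1)
  expect_identical(a, b)
  set.seed(3); x <- rqexp(1e5, 1.2, 1)
  ks <- suppressWarnings(ks.test(x, function(v) pqexp(v, 1.2, 1)))
  expect_gt(ks$p.value, 0.01)
  # mean formula 1/(lambda(3-2q)) = 2 for q = 1.25: within 3 SE at n = 1e6
  set.seed(4); y <- rqexp(1e6, 1.25, 1)
  se <- sqrt(12 / 1e6)  # Var = 2/((3-2q)(4-3q)) - mean^2 = 16 - 4
  expect_lt(abs(mean(y) - 2), 3 * se)
})

test_that("log-likelihood sums log densities and rejects out-of-support data", {
  expect_equal(qexp_loglik(3, 1, 1), -3, tolerance = 1e-12)
  expect_identical(qexp_loglik(c(1, 3), 0.5, 1), -Inf)  # 3 > support end 2
  expect_error(qexp_loglik(numeric(0), 1.2, 1), "empty")
  set.seed(5); x <- rqexp(200, 1.3, 0.5)
  expect_equal(qexp_loglik(x, 1.3, 0.5),
               sum(log(dqexp(x, 1.3, 0.5))), tolerance = 1e-12)
})

test_that("mean is 1/(lambda(3-2q)) and diverges at q = 1.5", {
  expect_equal(qexp_mean(1, 2), 0.5)
  m_quad <- integrate(function(x) x * dqexp(x, 1.25, 1), 0, Inf,
                      rel.tol = 1e-10)$value
  expect_equal(qexp_mean(1.25, 1), m_quad, tolerance = 1e-8)
  expect_equal(qexp_mean(1.25, 1), 2)
  expect_error(qexp_mean(1.5, 1), "diverges")
})

test_that("superstatistical q is the normalized second moment of the rates", {
  expect_identical(superstat_q(rep(2.5, 10)), 1)
  expect_equal(superstat_q(c(1, 3)), 1.25)
  set.seed(14); l <- rgamma(1e6, shape = 4, scale = 1)
  expect_equal(superstat_q(l), 1 + 1 / 4, tolerance = 0.01)
  expect_error(superstat_q(c(1, -1)), "positive")
  expect_error(superstat_q(numeric(0)))
  # Cauchy-Schwarz: always >= 1
  set.seed(15)
  for (r in 1:20) {
    expect_gte(superstat_q(rlnorm(50)), 1)
  }
})
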