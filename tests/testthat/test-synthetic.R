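test_that("the rate process is piecewise constant with Gamma statistics", {
  cfg <- superstat_config(a = 4, theta = 0.1, window_hours = 24,
                          n_hours = 24 * 10000, seasonal_amp = 0, seed = 1)
  lam <- gen_lambda_process(cfg)
  expect_length(lam, cfg$n_hours)
  expect_identical(length(rle(lam)$lengths), 10000L)  # one plateau/window
  # Gamma mean a*theta within 3 SE over 1e4 windows
  wmeans <- lam[seq(1, length(lam), by = 24)]
  se <- sqrt(4 * 0.1^2 / 10000)
  expect_lt(abs(mean(wmeans) - 0.4), 3 * se)
  # reproducible
  expect_identical(lam, gen_lambda_process(cfg))
  # partial final window
  cfg2 <- superstat_config(window_hours = 168, n_hours = 1000, seed = 2)
  expect_length(gen_lambda_process(cfg2), 1000L)
})

test_that("the closed-form marginal equals the numerically integrated mixture", {
  for (a in c(0.5, 2, 5, 20)) {
    for (theta in c(0.05, 1, 10)) {
      mq <- marginal_qexp(a, theta)
      xs <- c(0.01, 0.1, 1, 5, 20, 100) / (theta * a)  # span the scale
      expect_lt(max(abs(mixture_density_quad(xs, a, theta) -
                          dqexp(xs, mq[["q"]], mq[["lambda"]]))) /
                  max(dqexp(xs, mq[["q"]], mq[["lambda"]])), 1e-10)
    }
  }
  expect_equal(unname(marginal_qexp(2, 1)), c(4 / 3, 3))
  # vanishing fluctuations: q -> 1
  expect_lt(marginal_qexp(1e6, 1)[["q"]] - 1, 1e-5)
})

test_that("the marginal exponent differs from the rate-moment convention", {
  a <- 2
  set.seed(3); l <- rgamma(2e5, shape = a, scale = 1)
  q_moment <- superstat_q(l)        # <l^2>/<l>^2 = 1 + 1/a = 1.5
  q_marginal <- marginal_qexp(a, 1)[["q"]]  # (a+2)/(a+1) = 4/3
  expect_lt(abs(q_moment - 1.5), 0.02)
  expect_gt(abs(q_moment - q_marginal), 0.1)
})

test_that("generated concentrations follow the marginal q-exponential", {
  cfg <- superstat_config(a = 2, theta = 1, window_hours = 24,
                          n_hours = 2e5, seasonal_amp = 0, seed = 4)
  s <- gen_concentration_series(cfg)
  expect_true(all(s$value >= 0))
  mq <- marginal_qexp(2, 1)
  ks <- suppressWarnings(
    ks.test(s$value, function(v) pqexp(v, mq[["q"]], mq[["lambda"]])))
  expect_gt(ks$p.value, 0.01)
})

test_that("vanishing rate fluctuations recover exponential mean = sd", {
  cfg <- superstat_config(a = 1e6, theta = 5e-8, window_hours = 24,
                          n_hours = 1e5, seasonal_amp = 0, seed = 5)
  s <- gen_concentration_series(cfg)
  expect_lt(abs(sd(s$value) / mean(s$value) - 1), 0.02)
})

test_that("detection-limit censoring leaves no values between 0 and the limit", {
  cfg <- superstat_config(a = 2, theta = 1, n_hours = 5000,
                          seasonal_amp = 0, lod = 0.4, seed = 6)
  s <- gen_concentration_series(cfg)
  in_gap <- s$value > 0 & s$value < 0.4 & s$value != 0.2
  expect_identical(sum(in_gap), 0L)
  expect_gt(sum(s$value == 0.2), 0)  # the LOD/2 substitutes
})

test_that("the rate fluctuates on a slower time scale than concentrations", {
  cfg <- superstat_config(window_hours = 24, n_hours = 5000,
                          seasonal_amp = 0, seed = 7)
  lam <- gen_lambda_process(cfg)
  x <- gen_concentration_series(cfg)$value
  ac <- function(v) acf(v, lag.max = 1, plot = FALSE)$acf[2]
  expect_gt(ac(lam), ac(x))
})

test_that("the site ensemble is reproducible with deterministic category mix", {
  e1 <- gen_site_ensemble(20, n_hours = 200, wind_frac = 0.5, seed = 8)
  e2 <- gen_site_ensemble(20, n_hours = 200, wind_frac = 0.5, seed = 8)
  expect_identical(e1$observations, e2$observations)
  expect_identical(e1$sites, e2$sites)
  expect_identical(e1$wind, e2$wind)
  # category counts follow the configured proportions deterministically
  counts <- table(e1$truth$category)
  expect_identical(counts, table(e2$truth$category))
  expect_identical(nrow(e1$sites), 20L)
  # planted wind stations lie strictly inside the matching radius
  w <- e1$wind[!duplicated(e1$wind$station), ]
  d <- pmax(abs(w$latitude - e1$sites$latitude[1:10]),
            abs(w$longitude - e1$sites$longitude[1:10]))
  expect_true(all(d < 0.1))
  # truth table carries the closed-form marginal parameters
  expect_equal(e1$truth$q_true,
               (e1$truth$a + 2) / (e1$truth$a + 1))
  expect_equal(e1$truth$lambda_true,
               e1$truth$theta * (e1$truth$a + 1))
})
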