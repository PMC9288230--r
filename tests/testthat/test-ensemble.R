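test_that("station and area types combine into the seven environment categories", {
  expect_identical(classify_site("traffic", "urban"), "urban traffic")
  expect_identical(classify_site("traffic", "suburban"),
                   "suburban/rural traffic")
  expect_identical(classify_site("traffic", "rural"),
                   "suburban/rural traffic")
  expect_identical(classify_site("background", "rural"), "rural background")
  expect_identical(classify_site("industrial", "suburban"),
                   "suburban/rural industrial")
  # case-insensitive
  expect_identical(classify_site("Traffic", "URBAN"), "urban traffic")
  pairs <- expand.grid(st = c("traffic", "industrial", "background"),
                       at = c("urban", "suburban", "rural"),
                       stringsAsFactors = FALSE)
  cats <- classify_site(pairs$st, pairs$at)
  expect_length(unique(cats), 7L)
  expect_error(classify_site("mobile", "urban"), "unknown station type")
  expect_error(classify_site("traffic", "marine"), "unknown area type")
})

test_that("Beaufort classes follow the merged low-wind boundaries", {
  expect_identical(beaufort_class(0.3), "calm & light air")
  expect_identical(beaufort_class(2.0), "light breeze")
  expect_identical(beaufort_class(1.5), "calm & light air")  # boundary
  expect_identical(beaufort_class(4.0), "gentle breeze")
  expect_identical(beaufort_class(6.0), "moderate breeze")
  sweep <- beaufort_class(seq(0, 7.9, by = 0.05))
  expect_length(unique(sweep), 4L)
  expect_warning(out <- beaufort_class(9), "outside the four Beaufort")
  expect_true(is.na(out))
  expect_error(beaufort_class(-1), "non-negative")
})

test_that("weather-station matching uses a strict Chebyshev radius", {
  st <- data.frame(station = c("a", "b"),
                   latitude = c(50.09, 50.5), longitude = c(10.05, 10))
  expect_identical(match_weather_station(50, 10, st), "a")  # d = 0.09
  st2 <- data.frame(station = "c", latitude = 50.10, longitude = 10)
  expect_true(is.na(match_weather_station(50, 10, st2)))  # d = 0.10 excluded
  st3 <- data.frame(station = c("x", "y"),
                    latitude = c(50.02, 50.05), longitude = c(10, 10))
  expect_identical(match_weather_station(50, 10, st3), "x")  # nearest wins
  expect_true(is.na(match_weather_station(50, 10, st3[0, ])))
})

test_that("grouped lambda summaries match order-statistics oracles and rank by median", {
  one <- group_lambda_summary(2.5, "g")
  expect_equal(one$median_lambda, 2.5)
  expect_equal(one$q75 - one$q25, 0)

  s <- group_lambda_summary(c(1, 2, 3, 4, 5), rep("g", 5))
  expect_equal(s$median_lambda, 3)
  expect_equal(s$q25, 2)
  expect_equal(s$q75, 4)

  # ranking ascending by median, counts reported
  lam <- c(10, 12, 11, 1, 2, 3, 5, 6)
  grp <- c("high", "high", "high", "low", "low", "low", "mid", "mid")
  gs <- group_lambda_summary(lam, grp)
  expect_identical(gs$group, c("low", "mid", "high"))
  expect_identical(gs$n_sites, c(3L, 2L, 3L))
  expect_true(all(gs$q25 <= gs$median_lambda & gs$median_lambda <= gs$q75))
  expect_true(all(gs$q2.5 <= gs$q25 & gs$q75 <= gs$q97.5))

  # type-7 quantiles agree with sort-based oracle for odd n
  set.seed(31); v <- rlnorm(21)
  g <- group_lambda_summary(v, rep("g", 21))
  expect_equal(g$median_lambda, sort(v)[11])
  expect_error(group_lambda_summary(numeric(0), character(0)), "no finite")
})

test_that("the scatter table carries (q, log10 lambda) per fitted site", {
  df <- data.frame(site = c("a", "b", "c"), pollutant = "no2",
                   q = c(1.2, 0.9, 1.1), lambda = c(100, 1, -5))
  expect_warning(tab <- scatter_table(df, category = "urban traffic"),
                 "non-positive lambda")
  expect_identical(nrow(tab), 2L)
  expect_equal(tab$log10_lambda, c(2, 0))
  expect_identical(tab$category, rep("urban traffic", 2))
})
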