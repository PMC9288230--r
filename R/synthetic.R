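#' Configuration of the superstatistical synthetic-data generator
#'
#' Parameters of the generator that emulates an air-quality monitoring
#' site: hourly concentrations drawn from local exponential distributions
#' whose rate \eqn{\lambda(t)} fluctuates slowly (piecewise constant over
#' windows, one independent Gamma(a, theta) draw per window), so that the
#' long-run marginal is the q-exponential of \code{\link{marginal_qexp}}.
#' Optional multiplicative seasonal modulation of the mean concentration
#' \eqn{1/\lambda}, below-detection-limit substitution at LOD/2, and
#' stuck-value corruption (a run of one constant reading) exercise the
#' quality-control stage.
#'
#' Defaults describe a plausible European NO2-like site: \code{a = 2},
#' \code{theta = 0.05} (marginal mean 20 ug/m3, marginal q = 4/3),
#' weekly rate windows (168 h), two years of hourly data, 30\% seasonal
#' amplitude with a one-year period, and no corruption.
#'
#' @param a Gamma shape of the rate distribution (dimensionless, > 0).
#' @param theta Gamma scale of the rate distribution (1/(ug/m3), > 0).
#' @param window_hours length of the slow-rate windows in hours (>= 1).
#' @param n_hours series length in hours.
#' @param seasonal_amp seasonal amplitude in \eqn{[0, 1)} multiplying the
#'   mean concentration as \eqn{1 + amp\,\sin(2\pi t/period)}.
#' @param period_hours seasonal period in hours (default one year, 8760).
#' @param lod detection limit in ug/m3, or \code{NA} for none.
#' @param stuck_frac fraction of hours overwritten by a stuck instrument
#'   (0 disables).
#' @param stuck_value the constant reading emitted while stuck.
#' @param seed integer seed for reproducibility, or \code{NULL}.
#' @return an object of class \code{"superstat_config"}.
#' @export
superstat_config <- function(a = 2, theta = 0.05, window_hours = 168L,
                             n_hours = 17520L, seasonal_amp = 0.3,
                             period_hours = 8760L, lod = NA_real_,
                             stuck_frac = 0, stuck_value = 1,
                             seed = NULL) {
  stopifnot(a > 0, theta > 0, window_hours >= 1, n_hours >= 1,
            seasonal_amp >= 0, seasonal_amp < 1, period_hours > 0,
            stuck_frac >= 0, stuck_frac < 1)
  structure(list(a = a, theta = theta, window_hours = as.integer(window_hours),
                 n_hours = as.integer(n_hours), seasonal_amp = seasonal_amp,
                 period_hours = period_hours, lod = lod,
                 stuck_frac = stuck_frac, stuck_value = stuck_value,
                 seed = seed),
            class = "superstat_config")
}

#' Closed-form q-exponential marginal of the Gamma rate mixture
#'
#' Integrating the local exponential density over a Gamma(a, theta)
#' distribution of its rate gives exactly a q-exponential:
#' \deqn{\int_0^\infty \Gamma(\lambda; a, \theta)\,\lambda e^{-\lambda x}
#'   \,d\lambda = a\theta(1+\theta x)^{-(a+1)} = f_{q,\lambda_q}(x)}
#' with \eqn{q = (a+2)/(a+1)} and \eqn{\lambda_q = \theta(a+1)}. This is
#' the "true" parameter pair the per-site fit should recover on synthetic
#' data. It differs from the rate-moment index
#' \eqn{\langle\lambda^2\rangle/\langle\lambda\rangle^2 = 1 + 1/a} of
#' \code{\link{superstat_q}}, which characterises the rate fluctuations
#' themselves rather than the normalized marginal density; both
#' conventions coincide only in the limit \eqn{a \to \infty} (q = 1).
#'
#' @param a,theta Gamma shape and scale of the rate distribution.
#' @return named numeric vector \code{c(q, lambda)}.
#' @examples
#' marginal_qexp(a = 2, theta = 1)  # q = 4/3, lambda = 3
#' @export
marginal_qexp <- function(a, theta) {
  stopifnot(a > 0, theta > 0)
  c(q = (a + 2) / (a + 1), lambda = theta * (a + 1))
}

#' Generate the slowly fluctuating rate process
#'
#' Piecewise-constant \eqn{\lambda(t)}: one independent Gamma(a, theta)
#' draw per window of \code{window_hours}, held constant within the
#' window — the rate fluctuates on a time scale much longer than the
#' hourly concentration fluctuations. Seasonality multiplies the mean
#' concentration \eqn{1/\lambda} by \eqn{1 + amp\,\sin(2\pi t/period)},
#' i.e. divides the rate.
#'
#' @param config a \code{\link{superstat_config}}.
#' @return numeric vector of hourly rates, length \code{n_hours}.
#' @export
gen_lambda_process <- function(config) {
  stopifnot(inherits(config, "superstat_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  n_win <- ceiling(config$n_hours / config$window_hours)
  lam_win <- stats::rgamma(n_win, shape = config$a, scale = config$theta)
  lam <- rep(lam_win, each = config$window_hours)[seq_len(config$n_hours)]
  if (config$seasonal_amp > 0) {
    t <- seq_len(config$n_hours)
    lam <- lam / (1 + config$seasonal_amp *
                    sin(2 * pi * t / config$period_hours))
  }
  lam
}

#' Generate one synthetic hourly concentration series
#'
#' Draws hourly concentrations \eqn{x(t) \sim Exp(\lambda(t))} over the
#' rate process of \code{\link{gen_lambda_process}}, then applies
#' stuck-value corruption (a contiguous run of one constant value, if
#' configured) and LOD/2 substitution (if a detection limit is set).
#'
#' @param config a \code{\link{superstat_config}}.
#' @param site site code for the emitted series.
#' @param pollutant pollutant label.
#' @param station_type,area_type,latitude,longitude metadata attached to
#'   the series.
#' @return a \code{\link{site_series}} with hourly integer time index.
#' @export
gen_concentration_series <- function(config, site = "syn0001",
                                     pollutant = "no2",
                                     station_type = NA_character_,
                                     area_type = NA_character_,
                                     latitude = NA_real_,
                                     longitude = NA_real_) {
  lam <- gen_lambda_process(config)  # seeds the RNG if config$seed set
  n <- config$n_hours
  x <- stats::rexp(n, rate = lam)
  if (config$stuck_frac > 0) {
    run <- floor(config$stuck_frac * n)
    if (run > 0) {
      start <- sample.int(n - run + 1L, 1L)
      x[start:(start + run - 1L)] <- config$stuck_value
    }
  }
  s <- site_series(site, pollutant, time = seq_len(n), value = x,
                   lod = config$lod, station_type = station_type,
                   area_type = area_type, latitude = latitude,
                   longitude = longitude)
  if (!is.na(config$lod)) s <- substitute_lod(s)
  s
}

#' Generate a synthetic monitoring-site ensemble
#'
#' Builds a reproducible multi-site ensemble in the three tabular layouts
#' the pipeline consumes: hourly observations (date, site, variable,
#' value), site metadata (station/area types and coordinates spread over a
#' European-like bounding box) and hourly wind speeds from co-located
#' weather stations (placed within 0.1 degrees for a configurable fraction
#' of sites).
#'
#' Sites are assigned to environment categories deterministically in the
#' configured proportions; each category has its own Gamma rate parameters
#' \code{(a, theta)}, so the planted category medians of \eqn{\lambda} are
#' ordered by \code{theta} (polluted urban-traffic sites get the smallest
#' rates). Quality-control defects can be planted: short series, a high
#' below-LOD fraction (generated by an inflated detection limit), or a
#' stuck instrument; defect counts refer to otherwise-clean sites.
#'
#' @param n_sites number of sites.
#' @param categories data frame with columns \code{station_type},
#'   \code{area_type}, \code{prop} (mixing proportion), \code{a},
#'   \code{theta}; defaults cover all seven environment categories with
#'   \code{theta} increasing from urban traffic to rural background.
#' @param n_hours hours per clean site (default two years).
#' @param window_hours slow-rate window (default 168).
#' @param seasonal_amp,period_hours seasonal modulation (defaults 0.3,
#'   8760).
#' @param lod detection limit applied to every site (default 0.2 ug/m3, a
#'   typical chemiluminescence-analyzer limit, small enough that clean
#'   sites clear the below-LOD filter with margin).
#' @param pollutant pollutant label for all series.
#' @param wind_frac fraction of sites given a co-located weather station.
#' @param n_defect_short,n_defect_lod,n_defect_stuck numbers of planted
#'   defective sites (taken from the end of the site list).
#' @param seed integer seed; the ensemble is fully reproducible.
#' @return list with data frames \code{observations}, \code{sites},
#'   \code{wind}, and \code{truth} (per-site category, Gamma parameters,
#'   marginal \code{q_true}, \code{lambda_true}, planted \code{defect}).
#' @export
gen_site_ensemble <- function(n_sites, categories = default_categories(),
                              n_hours = 17520L, window_hours = 168L,
                              seasonal_amp = 0.3, period_hours = 8760L,
                              lod = 0.2, pollutant = "no2",
                              wind_frac = 0.8, n_defect_short = 0L,
                              n_defect_lod = 0L, n_defect_stuck = 0L,
                              seed = 1L) {
  stopifnot(n_sites >= 1,
            n_defect_short + n_defect_lod + n_defect_stuck <= n_sites)
  set.seed(seed)
  # deterministic category assignment in configured proportions
  counts <- floor(categories$prop / sum(categories$prop) * n_sites)
  while (sum(counts) < n_sites) counts[which.max(categories$prop)] <-
    counts[which.max(categories$prop)] + 1L
  cat_idx <- rep(seq_len(nrow(categories)), counts)[seq_len(n_sites)]

  site_id <- sprintf("syn%04d", seq_len(n_sites))
  lat <- round(stats::runif(n_sites, 36, 68), 4)
  lon <- round(stats::runif(n_sites, -9, 28), 4)
  defect <- rep("none", n_sites)
  if (n_defect_short > 0)
    defect[seq(n_sites - n_defect_short - n_defect_lod - n_defect_stuck + 1,
               length.out = n_defect_short)] <- "short"
  if (n_defect_lod > 0)
    defect[seq(n_sites - n_defect_lod - n_defect_stuck + 1,
               length.out = n_defect_lod)] <- "lod"
  if (n_defect_stuck > 0)
    defect[seq(n_sites - n_defect_stuck + 1,
               length.out = n_defect_stuck)] <- "stuck"

  obs <- vector("list", n_sites)
  t0 <- as.POSIXct("2017-01-01 00:00:00", tz = "UTC")
  for (i in seq_len(n_sites)) {
    ci <- cat_idx[i]
    nh <- if (defect[i] == "short") 4380L else as.integer(n_hours)
    a_i <- categories$a[ci]; th_i <- categories$theta[ci]
    # planted below-LOD defect: a detection limit placed at the 30th
    # percentile of the marginal, well above the 15% threshold
    lod_i <- if (defect[i] == "lod")
      (0.7^(-1 / (a_i + 1)) - 1) / th_i else lod
    cfg <- superstat_config(
      a = a_i, theta = th_i,
      window_hours = window_hours, n_hours = nh,
      seasonal_amp = seasonal_amp, period_hours = period_hours,
      lod = lod_i,
      stuck_frac = if (defect[i] == "stuck") 0.30 else 0,
      stuck_value = round(1 / (th_i * (a_i + 1)), 2),
      seed = NULL)
    s <- gen_concentration_series(cfg, site = site_id[i],
                                  pollutant = pollutant)
    obs[[i]] <- data.frame(
      date = format(t0 + 3600 * (seq_len(nh) - 1), "%Y-%m-%d %H:%M:%S"),
      site = site_id[i], variable = pollutant,
      value = round(s$value, 4), stringsAsFactors = FALSE)
  }

  sites <- data.frame(site = site_id,
                      site_type = categories$station_type[cat_idx],
                      site_area = categories$area_type[cat_idx],
                      latitude = lat, longitude = lon,
                      stringsAsFactors = FALSE)

  n_wind <- round(wind_frac * n_sites)
  wind <- NULL
  if (n_wind > 0) {
    wi <- seq_len(n_wind)
    wstation <- sprintf("wx%04d", wi)
    # co-located: strictly inside the 0.1-degree Chebyshev radius
    wlat <- lat[wi] + stats::runif(n_wind, -0.05, 0.05)
    wlon <- lon[wi] + stats::runif(n_wind, -0.05, 0.05)
    mean_ws <- stats::runif(n_wind, 0.5, 7.5)
    wdates <- format(t0 + 3600 * (seq_len(168L) - 1), "%Y-%m-%d %H:%M:%S")
    wind <- do.call(rbind, lapply(wi, function(j) data.frame(
      station = wstation[j], date = wdates,
      ws = round(pmax(stats::rnorm(168L, mean_ws[j], 0.5), 0), 2),
      latitude = wlat[j], longitude = wlon[j],
      stringsAsFactors = FALSE)))
  }

  mq <- t(vapply(cat_idx, function(ci)
    marginal_qexp(categories$a[ci], categories$theta[ci]), numeric(2)))
  truth <- data.frame(site = site_id,
                      category = classify_site(categories$station_type[cat_idx],
                                               categories$area_type[cat_idx]),
                      a = categories$a[cat_idx],
                      theta = categories$theta[cat_idx],
                      q_true = mq[, 1], lambda_true = mq[, 2],
                      defect = defect, stringsAsFactors = FALSE)

  list(observations = do.call(rbind, obs), sites = sites, wind = wind,
       truth = truth)
}

#' Default environment-category mix of the synthetic ensemble
#'
#' Seven categories with Gamma rate scale \code{theta} increasing from
#' urban traffic (most polluted, smallest rates) to rural background
#' (cleanest, largest rates), so the planted ordering of category
#' \eqn{\lambda} medians mirrors the field situation.
#'
#' @return data frame with columns \code{station_type}, \code{area_type},
#'   \code{prop}, \code{a}, \code{theta}.
#' @export
default_categories <- function() {
  data.frame(
    station_type = c("traffic", "traffic", "industrial", "industrial",
                     "background", "background", "background"),
    area_type = c("urban", "suburban", "urban", "rural",
                  "urban", "suburban", "rural"),
    prop = c(0.22, 0.08, 0.08, 0.07, 0.25, 0.15, 0.15),
    a = c(2, 2, 2.5, 2.5, 3, 3, 3),
    theta = c(0.008, 0.012, 0.012, 0.016, 0.015, 0.025, 0.05),
    stringsAsFactors = FALSE)
}
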