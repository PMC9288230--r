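#' Pipeline configuration
#'
#' Single source of truth for every pipeline constant: the quality-control
#' thresholds (minimum 8760 hourly points, below-LOD fraction 15\%,
#' repeated-value fraction 15\%), the kernel-density settings of the tail
#' cutoff, the optimizer settings of the q-exponential MLE, the Beaufort
#' class boundaries and the 0.1-degree weather-station matching radius.
#'
#' @param min_points minimum valid hourly points per site (365 days).
#' @param lod_frac maximum tolerated below-detection-limit fraction
#'   (exclusive: strictly more fails).
#' @param repeat_frac maximum tolerated single-value share (inclusive: at
#'   least this much fails).
#' @param kde_grid number of kernel-density evaluation points.
#' @param kde_bw bandwidth rule for \code{stats::density}.
#' @param mle_reltol,mle_maxit q-exponential MLE convergence controls.
#' @param beaufort_breaks upper boundaries (m/s) of the four wind classes.
#' @param match_radius_deg weather-station matching radius in degrees.
#' @param seed optional integer seed for stochastic stages.
#' @return an object of class \code{"pipeline_config"}.
#' @export
pipeline_config <- function(min_points = 8760L, lod_frac = 0.15,
                            repeat_frac = 0.15, kde_grid = 512L,
                            kde_bw = "nrd", mle_reltol = 1e-8,
                            mle_maxit = 500L,
                            beaufort_breaks = c(1.5, 3.3, 5.4, 7.9),
                            match_radius_deg = 0.1, seed = NULL) {
  stopifnot(min_points > 0, lod_frac > 0, repeat_frac > 0, kde_grid > 1,
            match_radius_deg > 0, length(beaufort_breaks) == 4L,
            !is.unsorted(beaufort_breaks))
  structure(list(min_points = as.integer(min_points), lod_frac = lod_frac,
                 repeat_frac = repeat_frac, kde_grid = as.integer(kde_grid),
                 kde_bw = kde_bw, mle_reltol = mle_reltol,
                 mle_maxit = as.integer(mle_maxit),
                 beaufort_breaks = beaufort_breaks,
                 match_radius_deg = match_radius_deg, seed = seed),
            class = "pipeline_config")
}

#' Read hourly observations into site series
#'
#' Parses the observations layout (columns \code{date}, \code{site},
#' \code{variable}, \code{value}; comma-separated, header mandatory, UTC
#' hour-start dates) into one \code{\link{site_series}} per (site,
#' pollutant) pair. Rows for pollutants outside \{no, no2, pm2.5, pm10\}
#' are dropped with a message; duplicated (site, variable, date) rows keep
#' the last occurrence with a warning; site metadata and a detection limit
#' can be attached from a sites table.
#'
#' @param obs path to a CSV file, or a data frame in the same layout.
#' @param sites optional data frame with columns \code{site},
#'   \code{site_type}, \code{site_area}, \code{latitude},
#'   \code{longitude}.
#' @param lod detection limit attached to every series (ug/m3), or
#'   \code{NA}.
#' @return named list of \code{\link{site_series}} (names
#'   \code{"site.pollutant"}).
#' @export
read_observations <- function(obs, sites = NULL, lod = NA_real_) {
  if (is.character(obs)) {
    obs <- utils::read.csv(obs, stringsAsFactors = FALSE)
  }
  need <- c("date", "site", "variable", "value")
  if (!all(need %in% names(obs)))
    stop("observations must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  known <- c("no", "no2", "pm2.5", "pm10")
  obs$variable <- tolower(obs$variable)
  drop <- !obs$variable %in% known
  if (any(drop)) {
    message(sum(drop), " row(s) with out-of-scope pollutants ignored")
    obs <- obs[!drop, , drop = FALSE]
  }
  key <- paste(obs$site, obs$variable, obs$date)
  if (anyDuplicated(key)) {
    warning(sum(duplicated(key)),
            " duplicated (site, variable, date) row(s); keeping the last",
            call. = FALSE)
    obs <- obs[!duplicated(key, fromLast = TRUE), , drop = FALSE]
  }
  out <- list()
  for (grp in split(obs, paste(obs$site, obs$variable, sep = "."))) {
    tm <- as.POSIXct(grp$date, tz = "UTC")
    o <- order(tm)
    st <- grp$site[1]
    meta <- if (!is.null(sites)) sites[match(st, sites$site), ] else NULL
    out[[paste(st, grp$variable[1], sep = ".")]] <- site_series(
      site = st, pollutant = grp$variable[1],
      time = tm[o], value = as.numeric(grp$value)[o], lod = lod,
      station_type = if (!is.null(meta)) meta$site_type else NA_character_,
      area_type = if (!is.null(meta)) meta$site_area else NA_character_,
      latitude = if (!is.null(meta)) meta$latitude else NA_real_,
      longitude = if (!is.null(meta)) meta$longitude else NA_real_)
  }
  out[order(names(out))]
}

#' Run the full tail-statistics pipeline over an ensemble
#'
#' Composes the stages over all sites: quality control, density-peak tail
#' extraction, five-family maximum-likelihood fitting with log-likelihood
#' model selection, environment classification, optional wind-class
#' assignment via nearest-weather-station matching, and grouped
#' width-parameter summaries. Per-site failures are recorded and the run
#' continues.
#'
#' @param series_list list of \code{\link{site_series}} (e.g. from
#'   \code{\link{read_observations}}).
#' @param wind optional data frame with columns \code{station},
#'   \code{date}, \code{ws}, \code{latitude}, \code{longitude} (hourly
#'   wind speeds per weather station).
#' @param config a \code{\link{pipeline_config}}.
#' @return an object of class \code{"pipeline_result"}: list with
#'   \describe{
#'     \item{qc}{data frame of per-site QC outcomes;}
#'     \item{results}{data frame of per-site fits (x_peak, n_tail, q,
#'       lambda, per-family log-likelihoods, best family, raw mean/sd,
#'       category, wind class);}
#'     \item{failures}{data frame of flagged per-site failures;}
#'     \item{mean_loglik}{named mean log-likelihood per family across
#'       successfully fitted sites;}
#'     \item{summary_category, summary_wind}{grouped lambda summaries.}
#'   }
#' @export
run_pipeline <- function(series_list, wind = NULL,
                         config = pipeline_config()) {
  if (!is.null(config$seed)) set.seed(config$seed)
  qc_rows <- list(); res_rows <- list(); fail_rows <- list()

  wstations <- NULL
  if (!is.null(wind)) {
    agg <- stats::aggregate(ws ~ station, data = wind, FUN = mean)
    pos <- wind[!duplicated(wind$station),
                c("station", "latitude", "longitude")]
    wstations <- merge(pos, agg, by = "station")
  }

  for (s in series_list) {
    rep <- run_qc(s, config)
    qc_rows[[length(qc_rows) + 1L]] <- data.frame(
      site = rep$site, pollutant = rep$pollutant, n_points = rep$n_points,
      frac_below_lod = if (is.na(rep$frac_below_lod)) NA_real_ else
        rep$frac_below_lod,
      max_value_frac = rep$max_value_frac, passed = rep$passed,
      reasons = paste(rep$reasons, collapse = ";"),
      stringsAsFactors = FALSE)
    if (!rep$passed) {
      fail_rows[[length(fail_rows) + 1L]] <- data.frame(
        site = rep$site, pollutant = rep$pollutant, stage = "qc",
        reason = paste(rep$reasons, collapse = ";"),
        stringsAsFactors = FALSE)
      next
    }
    sf <- fit_site(rep$series, config, qc = FALSE)
    if (!sf$ok) {
      fail_rows[[length(fail_rows) + 1L]] <- data.frame(
        site = sf$site, pollutant = sf$pollutant, stage = "fit",
        reason = sf$error, stringsAsFactors = FALSE)
      next
    }
    category <- if (!is.na(s$station_type) && !is.na(s$area_type))
      classify_site(s$station_type, s$area_type) else NA_character_
    wind_class <- NA_character_
    if (!is.null(wstations) && is.finite(s$latitude)) {
      wm <- match_weather_station(s$latitude, s$longitude, wstations,
                                  config$match_radius_deg)
      if (!is.na(wm)) {
        mws <- wstations$ws[wstations$station == wm]
        wind_class <- suppressWarnings(
          beaufort_class(mws, config$beaufort_breaks))
      }
    }
    ll <- vapply(sf$fits, `[[`, numeric(1), "loglik")
    res_rows[[length(res_rows) + 1L]] <- data.frame(
      site = sf$site, pollutant = sf$pollutant,
      x_peak = sf$tailcut$x_peak, n_tail = sf$tailcut$n_tail,
      q = sf$q, lambda = sf$lambda,
      loglik_exp = ll[["exponential"]], loglik_gamma = ll[["gamma"]],
      loglik_weibull = ll[["weibull"]],
      loglik_lognormal = ll[["lognormal"]],
      loglik_qexp = ll[["qexponential"]],
      best_family = sf$best_family, mean = sf$mean, sd = sf$sd,
      category = category, wind_class = wind_class,
      stringsAsFactors = FALSE)
  }

  results <- if (length(res_rows)) do.call(rbind, res_rows) else NULL
  mean_ll <- if (!is.null(results)) c(
    exponential = mean(results$loglik_exp),
    gamma = mean(results$loglik_gamma),
    weibull = mean(results$loglik_weibull),
    lognormal = mean(results$loglik_lognormal),
    qexponential = mean(results$loglik_qexp)) else NULL

  sum_cat <- if (!is.null(results) && any(!is.na(results$category)))
    group_lambda_summary(results$lambda, results$category) else NULL
  sum_wind <- if (!is.null(results) && any(!is.na(results$wind_class)))
    group_lambda_summary(results$lambda, results$wind_class) else NULL

  structure(list(
    qc = do.call(rbind, qc_rows),
    results = results,
    failures = if (length(fail_rows)) do.call(rbind, fail_rows) else NULL,
    mean_loglik = mean_ll,
    summary_category = sum_cat, summary_wind = sum_wind,
    config = config),
    class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  n_all <- nrow(x$qc)
  n_pass <- sum(x$qc$passed)
  n_fit <- if (is.null(x$results)) 0L else nrow(x$results)
  cat(sprintf("air-pollution tail-statistics pipeline: %d series, %d passed QC, %d fitted\n",
              n_all, n_pass, n_fit))
  if (!is.null(x$mean_loglik)) {
    cat("mean log-likelihood across sites (best family first):\n")
    print(round(sort(x$mean_loglik, decreasing = TRUE), 2))
  }
  if (!is.null(x$summary_category)) {
    cat("lambda medians by environment category (ascending):\n")
    print(transform(x$summary_category,
                    median_lambda = signif(median_lambda, 4))[
                      , c("group", "n_sites", "median_lambda")])
  }
  invisible(x)
}

#' Write pipeline outputs as CSV files
#'
#' @param result a \code{\link{run_pipeline}} result.
#' @param outdir output directory (created if absent).
#' @return invisibly, the paths written.
#' @export
write_results <- function(result, outdir) {
  stopifnot(inherits(result, "pipeline_result"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  wr <- function(df, name) {
    if (is.null(df)) return()
    p <- file.path(outdir, name)
    utils::write.csv(df, p, row.names = FALSE)
    paths <<- c(paths, p)
  }
  wr(result$qc, "qc_report.csv")
  wr(result$results, "results.csv")
  wr(result$failures, "failures.csv")
  wr(result$summary_category, "summary_category.csv")
  wr(result$summary_wind, "summary_wind.csv")
  invisible(paths)
}
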