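#' Construct an hourly site concentration series
#'
#' Container for one monitoring site's hourly concentrations of a single
#' pollutant, with station metadata. Timestamps must be strictly
#' increasing; missing hours are simply absent or carried as \code{NA}
#' values.
#'
#' @param site site code (e.g. \code{"gb0682a"}).
#' @param pollutant one of \code{"no"}, \code{"no2"}, \code{"pm2.5"},
#'   \code{"pm10"}.
#' @param time POSIXct timestamps (UTC, hour start) or numeric hour index;
#'   strictly increasing.
#' @param value concentrations in ug/m3; \code{NA} allowed.
#' @param lod detection limit in ug/m3, or \code{NA} if unknown.
#' @param station_type one of \code{"traffic"}, \code{"industrial"},
#'   \code{"background"} (or \code{NA}).
#' @param area_type one of \code{"urban"}, \code{"suburban"},
#'   \code{"rural"} (or \code{NA}).
#' @param latitude,longitude WGS84 coordinates in degrees (or \code{NA}).
#' @return an object of class \code{"site_series"}.
#' @export
site_series <- function(site, pollutant, time, value, lod = NA_real_,
                        station_type = NA_character_,
                        area_type = NA_character_,
                        latitude = NA_real_, longitude = NA_real_) {
  pollutant <- match.arg(tolower(pollutant), c("no", "no2", "pm2.5", "pm10"))
  if (length(time) != length(value))
    stop("'time' and 'value' must have the same length", call. = FALSE)
  if (length(time) > 1L && any(diff(as.numeric(time)) <= 0))
    stop("timestamps must be strictly increasing", call. = FALSE)
  if (any(is.infinite(value), na.rm = TRUE))
    stop("values must be finite where present", call. = FALSE)
  structure(list(site = site, pollutant = pollutant, time = time,
                 value = as.numeric(value), lod = lod,
                 station_type = station_type, area_type = area_type,
                 latitude = latitude, longitude = longitude,
                 n_below_lod = NA_integer_),
            class = "site_series")
}

#' @export
print.site_series <- function(x, ...) {
  cat(sprintf("site series %s / %s: %d hours (%d valid)\n",
              x$site, x$pollutant, length(x$value), sum(!is.na(x$value))))
  if (!is.na(x$lod)) cat(sprintf("  detection limit %.3g ug/m3\n", x$lod))
  if (!is.na(x$station_type))
    cat(sprintf("  %s / %s at (%.3f, %.3f)\n", x$station_type, x$area_type,
                x$latitude, x$longitude))
  invisible(x)
}

#' Replace below-detection-limit values by LOD/2
#'
#' Values below the detection limit, including negative readings, are
#' replaced by half the detection limit, the convention for censored
#' monitoring data. The number of substitutions is recorded on the series
#' (field \code{n_below_lod}).
#'
#' @param series a \code{\link{site_series}} with \code{lod} set.
#' @return the series with substituted values.
#' @examples
#' s <- site_series("s1", "no2", 1:3, c(-0.2, 0.1, 5), lod = 0.4)
#' substitute_lod(s)$value  # 0.2 0.2 5.0
#' @export
substitute_lod <- function(series) {
  if (is.na(series$lod)) stop("series has no detection limit", call. = FALSE)
  if (series$lod <= 0) stop("detection limit must be positive", call. = FALSE)
  below <- !is.na(series$value) & series$value < series$lod
  series$value[below] <- series$lod / 2
  series$n_below_lod <- sum(below)
  series
}

#' Site quality-control filters
#'
#' Three filters on an hourly concentration series:
#' \describe{
#'   \item{\code{filter_length}}{at least 8760 valid points (365 days of
#'     hourly data), so that a full seasonal cycle is covered.}
#'   \item{\code{filter_lod_fraction}}{fail if \emph{more than} 15\% of
#'     values fall below the detection limit (strict inequality; 15\% is
#'     the accepted substitution limit).}
#'   \item{\code{filter_repeats}}{fail if any single value accounts for
#'     \emph{at least} 15\% of valid measurements (inclusive) — a stuck or
#'     low-precision instrument.}
#' }
#'
#' @param series a \code{\link{site_series}}.
#' @param min_points,max_frac threshold overrides; defaults are the
#'   pipeline constants (see \code{\link{pipeline_config}}).
#' @return logical: \code{TRUE} if the series passes the filter.
#' @name qc_filters
NULL

qc_valid_values <- function(series) series$value[!is.na(series$value)]

#' @rdname qc_filters
#' @export
filter_length <- function(series, min_points = 8760L) {
  length(qc_valid_values(series)) >= min_points
}

qc_lod_fraction <- function(series) {
  v <- qc_valid_values(series)
  if (length(v) == 0L || is.na(series$lod)) return(NA_real_)
  # after substitution the below-LOD readings sit exactly at LOD/2
  mean(v < series$lod)
}

#' @rdname qc_filters
#' @export
filter_lod_fraction <- function(series, max_frac = 0.15) {
  frac <- qc_lod_fraction(series)
  if (is.na(frac)) return(NA)
  !(frac > max_frac)
}

qc_max_value_fraction <- function(series) {
  v <- qc_valid_values(series)
  if (length(v) == 0L) return(NA_real_)
  max(table(v)) / length(v)
}

#' @rdname qc_filters
#' @export
filter_repeats <- function(series, max_frac = 0.15) {
  frac <- qc_max_value_fraction(series)
  if (is.na(frac)) return(FALSE)
  !(frac >= max_frac)
}

#' Run all quality-control filters on a site series
#'
#' Applies LOD/2 substitution (when a detection limit is known) and then
#' the three filters of \code{\link{qc_filters}}. All failed filters are
#' reported, not just the first. When no detection limit is available the
#' below-LOD filter is skipped and noted in the report rather than guessed.
#'
#' @param series a \code{\link{site_series}}.
#' @param config a \code{\link{pipeline_config}} supplying the thresholds.
#' @return an object of class \code{"qc_report"}: list with \code{site},
#'   \code{pollutant}, \code{n_points}, \code{frac_below_lod},
#'   \code{max_value_frac}, \code{passed}, \code{reasons} (character vector
#'   of failed filter names), \code{skipped} and the substituted
#'   \code{series}.
#' @export
run_qc <- function(series, config = pipeline_config()) {
  if (!inherits(series, "site_series"))
    stop("'series' must be a site_series", call. = FALSE)
  skipped <- character(0)
  if (!is.na(series$lod)) {
    series <- substitute_lod(series)
  } else {
    skipped <- "lod_fraction"
  }
  reasons <- character(0)
  if (!filter_length(series, config$min_points)) reasons <- c(reasons, "length")
  lod_ok <- filter_lod_fraction(series, config$lod_frac)
  if (isFALSE(lod_ok)) reasons <- c(reasons, "lod_fraction")
  if (!filter_repeats(series, config$repeat_frac)) reasons <- c(reasons, "repeats")
  structure(list(site = series$site, pollutant = series$pollutant,
                 n_points = length(qc_valid_values(series)),
                 frac_below_lod = qc_lod_fraction(series),
                 max_value_frac = qc_max_value_fraction(series),
                 passed = length(reasons) == 0L,
                 reasons = reasons, skipped = skipped,
                 series = series),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("QC %s / %s: %s\n", x$site, x$pollutant,
              if (x$passed) "PASSED" else
                paste("FAILED:", paste(x$reasons, collapse = ", "))))
  cat(sprintf("  n = %d, below-LOD fraction = %s, max value share = %.3f\n",
              x$n_points,
              if (is.na(x$frac_below_lod)) "unknown (no LOD)" else
                sprintf("%.3f", x$frac_below_lod),
              x$max_value_frac))
  if (length(x$skipped))
    cat("  skipped filters:", paste(x$skipped, collapse = ", "), "\n")
  invisible(x)
}
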