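#' Combined environment category of a monitoring site
#'
#' Combines the station type (traffic, industrial, background — by
#' predominant emission source) with the surrounding area type (urban,
#' suburban, rural — by building density) into one of seven environment
#' categories: the nine raw combinations collapse because suburban and
#' rural are merged for traffic and industrial stations.
#'
#' @param station_type character vector in \{traffic, industrial,
#'   background\} (case-insensitive).
#' @param area_type character vector in \{urban, suburban, rural\}
#'   (case-insensitive).
#' @return character vector of category labels.
#' @examples
#' classify_site("traffic", "urban")     # "urban traffic"
#' classify_site("traffic", "rural")     # "suburban/rural traffic"
#' @export
classify_site <- function(station_type, area_type) {
  st <- tolower(trimws(station_type))
  at <- tolower(trimws(area_type))
  if (any(!st %in% c("traffic", "industrial", "background")))
    stop("unknown station type: ",
         paste(unique(st[!st %in% c("traffic", "industrial", "background")]),
               collapse = ", "), call. = FALSE)
  if (any(!at %in% c("urban", "suburban", "rural")))
    stop("unknown area type: ",
         paste(unique(at[!at %in% c("urban", "suburban", "rural")]),
               collapse = ", "), call. = FALSE)
  merged <- ifelse(at == "urban", "urban", "suburban/rural")
  ifelse(st == "background", paste(at, "background"),
         paste(merged, st))
}

#' Beaufort wind-force class of a site
#'
#' Classifies a site's mean wind speed into the four lowest Beaufort
#' classes, with calm and light air merged: calm & light air
#' \eqn{[0, 1.5]} m/s, light breeze \eqn{(1.5, 3.3]}, gentle breeze
#' \eqn{(3.3, 5.4]}, moderate breeze \eqn{(5.4, 7.9]}. Speeds above
#' 7.9 m/s fall outside the four classes considered and return \code{NA}
#' with a warning.
#'
#' @param mean_ws mean wind speed in m/s, non-negative.
#' @param breaks upper class boundaries in m/s.
#' @return character vector of class labels (\code{NA} above the top
#'   boundary).
#' @examples
#' beaufort_class(c(0.3, 2, 4, 6))
#' @export
beaufort_class <- function(mean_ws, breaks = c(1.5, 3.3, 5.4, 7.9)) {
  if (any(!is.finite(mean_ws) | mean_ws < 0))
    stop("wind speeds must be finite and non-negative", call. = FALSE)
  labels <- c("calm & light air", "light breeze", "gentle breeze",
              "moderate breeze")
  out <- as.character(cut(mean_ws, breaks = c(0, breaks), labels = labels,
                          include.lowest = TRUE, right = TRUE))
  if (anyNA(out))
    warning(sum(is.na(out)), " site(s) with mean wind speed above ",
            breaks[4], " m/s fall outside the four Beaufort classes ",
            "considered", call. = FALSE)
  out
}

#' Match a pollution site to its nearest weather station
#'
#' Nearest station by Chebyshev distance
#' \eqn{\max(|\Delta lat|, |\Delta lon|)} in degrees; a match requires
#' that distance to be strictly less than the radius (a station exactly at
#' the radius is rejected).
#'
#' @param site_lat,site_lon site coordinates in WGS84 degrees.
#' @param stations data frame with columns \code{station},
#'   \code{latitude}, \code{longitude}.
#' @param radius_deg matching radius in degrees (default 0.1).
#' @return the matched station identifier, or \code{NA} if none qualifies.
#' @export
match_weather_station <- function(site_lat, site_lon, stations,
                                  radius_deg = 0.1) {
  if (is.null(stations) || nrow(stations) == 0L) return(NA_character_)
  d <- pmax(abs(stations$latitude - site_lat),
            abs(stations$longitude - site_lon))
  i <- which.min(d)
  if (d[i] < radius_deg) as.character(stations$station[i]) else NA_character_
}

#' Grouped summaries of the fitted width parameter
#'
#' Per-group summary of the q-exponential width parameter \eqn{\lambda}
#' across sites — the tabular content behind violin plots: site count,
#' median, interquartile range and central 95\% percentile interval
#' (linear-interpolation quantiles, type 7). Groups are ranked by median
#' \eqn{\lambda} from lowest (most polluted) to highest.
#'
#' @param lambda fitted width parameters, one per site.
#' @param group grouping labels (environment category or Beaufort class),
#'   same length as \code{lambda}.
#' @return data frame with columns \code{group}, \code{n_sites},
#'   \code{median_lambda}, \code{q25}, \code{q75}, \code{q2.5},
#'   \code{q97.5}, sorted by \code{median_lambda} ascending.
#' @export
group_lambda_summary <- function(lambda, group) {
  keep <- is.finite(lambda) & !is.na(group)
  lambda <- lambda[keep]; group <- as.character(group)[keep]
  if (length(lambda) == 0L) stop("no finite lambda values", call. = FALSE)
  gs <- split(lambda, group)
  out <- do.call(rbind, lapply(names(gs), function(g) {
    v <- gs[[g]]
    qs <- stats::quantile(v, c(0.025, 0.25, 0.5, 0.75, 0.975),
                          type = 7, names = FALSE)
    data.frame(group = g, n_sites = length(v), median_lambda = qs[3],
               q25 = qs[2], q75 = qs[4], q2.5 = qs[1], q97.5 = qs[5],
               stringsAsFactors = FALSE)
  }))
  out <- out[order(out$median_lambda), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Parameter-scatter table of per-site fits
#'
#' The \eqn{(q, \log_{10}\lambda)} tuples behind the parameter-plane
#' scatter plots, one row per successfully fitted site, with environment
#' category attached. Rows with non-positive \eqn{\lambda} are dropped
#' with a warning.
#'
#' @param site_fits list of \code{\link{fit_site}} results, or a results
#'   data frame with columns \code{site}, \code{pollutant}, \code{q},
#'   \code{lambda}.
#' @param category optional per-site environment labels (recycled against
#'   rows).
#' @return data frame with columns \code{site}, \code{pollutant},
#'   \code{q}, \code{log10_lambda}, \code{category}.
#' @export
scatter_table <- function(site_fits, category = NA_character_) {
  if (is.data.frame(site_fits)) {
    df <- site_fits[, c("site", "pollutant", "q", "lambda")]
  } else {
    ok <- vapply(site_fits, `[[`, logical(1), "ok")
    site_fits <- site_fits[ok]
    df <- data.frame(
      site = vapply(site_fits, `[[`, character(1), "site"),
      pollutant = vapply(site_fits, `[[`, character(1), "pollutant"),
      q = vapply(site_fits, `[[`, numeric(1), "q"),
      lambda = vapply(site_fits, `[[`, numeric(1), "lambda"),
      stringsAsFactors = FALSE)
  }
  df$category <- rep_len(category, nrow(df))
  bad <- !is.finite(df$lambda) | df$lambda <= 0
  if (any(bad)) {
    warning(sum(bad), " row(s) with non-positive lambda dropped",
            call. = FALSE)
    df <- df[!bad, , drop = FALSE]
  }
  data.frame(site = df$site, pollutant = df$pollutant, q = df$q,
             log10_lambda = log10(df$lambda), category = df$category,
             stringsAsFactors = FALSE, row.names = NULL)
}
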