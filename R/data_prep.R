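#' Reference series for temporal correction
#'
#' A fixed background reference site (away from traffic sources) whose
#' time series is used to remove campaign-wide temporal variation from
#' mobile observations.
#'
#' @param timestamps POSIXct vector.
#' @param values concentrations at the reference site.
#' @return A \code{reference_series} object; \code{campaign_mean} is the
#'   mean of \code{values}.
#' @export
reference_series <- function(timestamps, values) {
  stopifnot(length(timestamps) == length(values), length(values) >= 1)
  assert_finite_nonneg(values, "reference values")
  structure(list(timestamps = as.POSIXct(timestamps, tz = "UTC"),
                 values = as.numeric(values),
                 campaign_mean = mean(values)),
            class = "reference_series")
}

#' Temporally correct mobile observations against a reference site
#'
#' Removes shared temporal variation by comparing the reference site's
#' mean over the observation's averaging window (by default the calendar
#' hour) with the reference campaign mean. Additive mode subtracts the
#' window anomaly; multiplicative mode rescales by the ratio of campaign
#' to window mean (conventional for particle counts).
#'
#' @param observations data frame with \code{timestamp} (POSIXct) and
#'   \code{value}.
#' @param reference a \code{\link{reference_series}}.
#' @param mode "additive" or "multiplicative".
#' @param window "hour" (calendar hour, default) or a numeric window
#'   width in seconds centered on the observation.
#' @return Corrected observations; rows without reference coverage are
#'   dropped with the count logged (attribute \code{n_dropped}).
#' @export
temporal_correct <- function(observations, reference,
                             mode = c("additive", "multiplicative"),
                             window = "hour") {
  mode <- match.arg(mode)
  stopifnot(inherits(reference, "reference_series"))
  ts_obs <- as.POSIXct(observations$timestamp, tz = "UTC")
  if (identical(window, "hour")) {
    key_obs <- format(ts_obs, "%Y-%m-%d %H", tz = "UTC")
    key_ref <- format(reference$timestamps, "%Y-%m-%d %H", tz = "UTC")
    ref_mean <- tapply(reference$values, key_ref, mean)
    win_mean <- as.numeric(ref_mean[key_obs])
  } else {
    stopifnot(is.numeric(window), window > 0)
    tr <- as.numeric(reference$timestamps)
    to <- as.numeric(ts_obs)
    win_mean <- vapply(to, function(t0) {
      sel <- abs(tr - t0) <= window / 2
      if (!any(sel)) NA_real_ else mean(reference$values[sel])
    }, 0)
  }
  covered <- !is.na(win_mean)
  log_count(sum(!covered), "observation(s) without reference coverage dropped")
  observations <- observations[covered, , drop = FALSE]
  win_mean <- win_mean[covered]
  cm <- reference$campaign_mean
  if (mode == "additive") {
    observations$value <- observations$value - (win_mean - cm)
  } else {
    if (any(win_mean <= 0)) {
      stop("reference window mean <= 0 in multiplicative mode")
    }
    observations$value <- observations$value * cm / win_mean
  }
  attr(observations, "n_dropped") <- sum(!covered)
  observations
}

#' Aggregate snapped observations to segment level
#'
#' Per (segment, pollutant): the arithmetic mean concentration, the
#' observation count, and the number of drive-passes, defined as the
#' count of distinct calendar dates with at least one observation.
#'
#' @param observations snapped observations (non-missing
#'   \code{segment_id}).
#' @param tz timezone used to resolve the local calendar date
#'   (default "UTC").
#' @return data frame with \code{segment_id}, \code{pollutant},
#'   \code{mean_conc}, \code{n_obs}, \code{n_drive_passes}.
#' @export
aggregate_segments <- function(observations, tz = "UTC") {
  if (any(is.na(observations$segment_id))) {
    stop("all observations must carry a segment_id; snap first")
  }
  dt <- format(as.POSIXct(observations$timestamp, tz = "UTC"), "%Y-%m-%d",
               tz = tz)
  key <- interaction(observations$segment_id, observations$pollutant,
                     drop = TRUE, sep = "\r")
  agg <- data.frame(
    key = levels(key),
    mean_conc = as.numeric(tapply(observations$value, key, mean)),
    n_obs = as.integer(tapply(observations$value, key, length)),
    n_drive_passes = as.integer(
      tapply(dt, key, function(d) length(unique(d)))),
    stringsAsFactors = FALSE)
  parts <- strsplit(agg$key, "\r", fixed = TRUE)
  agg$segment_id <- vapply(parts, `[`, "", 1)
  agg$pollutant <- vapply(parts, `[`, "", 2)
  agg$key <- NULL
  agg <- agg[order(agg$segment_id, agg$pollutant),
             c("segment_id", "pollutant", "mean_conc", "n_obs",
               "n_drive_passes")]
  rownames(agg) <- NULL
  stopifnot(all(agg$n_drive_passes <= agg$n_obs), all(agg$n_obs >= 1))
  agg
}

#' Match long-term monitoring sites to nearby road segments
#'
#' A segment matches a site when its minimum Euclidean distance to the
#' site is at most \code{radius} meters (30 m in the standard protocol).
#' Sites without any match are flagged.
#'
#' @param sites data frame with \code{site_id}, \code{x}, \code{y},
#'   \code{pollutant}, \code{value}.
#' @param segments a \code{road_segments} object.
#' @param radius matching radius in meters.
#' @return \code{sites} with a list column \code{matched_segment_ids} and
#'   logical \code{unmatched}.
#' @export
match_sites_to_segments <- function(sites, segments, radius = 30) {
  stopifnot(radius > 0)
  pts <- cbind(sites$x, sites$y)
  D <- dist_points_to_polylines(pts, segments$vertices)
  sites$matched_segment_ids <- lapply(seq_len(nrow(sites)), function(i) {
    segments$segment_id[D[i, ] <= radius]
  })
  sites$unmatched <- lengths(sites$matched_segment_ids) == 0
  log_count(sum(sites$unmatched), "site(s) without a segment within radius")
  sites
}
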