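#' Synthetic scene configuration
#'
#' A synthetic study area: a rectangular grid of streets (every
#' \code{major_every}-th street is a major road), segmented into
#' \code{segment_length}-meter road segments, each carrying traffic,
#' population and land-use covariates with declared effect directions
#' and a true long-term concentration surface
#' \code{y* = intercept + linear predictor + mild nonlinearity +
#' spatially correlated noise}, all positive. The default scale mimics
#' an NO2-like pollutant (roughly 15-45 ug/m3 across an urban area).
#'
#' @param n_streets streets per direction (default 8; with 250 m
#'   spacing this yields 560 segments of 50 m).
#' @param street_spacing meters between parallel streets.
#' @param segment_length target segment length in meters (default 50).
#' @param major_every every k-th street is a major road.
#' @param intercept background concentration level.
#' @param coefficients named true effects on the linear scale; names
#'   must match the generated covariates.
#' @param nonlinear_coef coefficient of the quadratic traffic term (the
#'   mild nonlinearity).
#' @param spatial_sd standard deviation of the spatially correlated
#'   noise field (smoothed white noise).
#' @param spatial_range kernel bandwidth (m) of the noise smoothing.
#' @param seed integer seed; the scene is fully reproducible from it.
#' @return a \code{scene_config} object.
#' @export
scene_config <- function(n_streets = 8, street_spacing = 250,
                         segment_length = 50, major_every = 4,
                         intercept = 16,
                         coefficients = c(traffic_intensity = 6,
                                          major_road_100 = 3,
                                          major_road_500 = 1.5,
                                          population = 4,
                                          industry = 3,
                                          green = -3),
                         nonlinear_coef = 2,
                         spatial_sd = 1.5, spatial_range = 400,
                         seed = 1) {
  stopifnot(n_streets >= 2, street_spacing > 0, segment_length > 0)
  structure(list(n_streets = n_streets, street_spacing = street_spacing,
                 segment_length = segment_length, major_every = major_every,
                 intercept = intercept, coefficients = coefficients,
                 nonlinear_coef = nonlinear_coef, spatial_sd = spatial_sd,
                 spatial_range = spatial_range, seed = as.integer(seed)),
            class = "scene_config")
}

#' Domain-shift configuration for the mobile campaign
#'
#' Encodes how mobile on-road daytime measurements differ from
#' long-term near-road means: a traffic-dependent multiplicative
#' on-road inflation, an additive daytime bias, campaign temporal
#' variation shared with the reference site, per-pass sensor noise, and
#' the layout/noise of the sparse long-term network. The two presets
#' calibrate the mobile/long-term mean ratio to the published campaign
#' summaries (about +5% for the NO2-like case with 82 sites, about
#' +18% for the UFP-like case with 17 sites); these are generator
#' defaults, explicitly not ground truth.
#'
#' @param pollutant "no2" or "ufp" preset.
#' @param on_road_inflation_slope slope a of the multiplicative bias
#'   \code{1 + a * traffic_norm} (traffic_norm in [0, 1]).
#' @param daytime_bias additive concentration bias on mobile passes.
#' @param on_road_excess_sd standard deviation of the persistent
#'   per-segment on-road excess: the site-specific discrepancy between
#'   what is measured on the carriageway and the near-road long-term
#'   level (street-canyon geometry, instrument differences). The
#'   presets calibrate it so the correlation between mobile aggregates
#'   and long-term values at matched locations lands near the published
#'   campaign values (moderate for the NO2-like case, weak for the
#'   UFP-like case); it also makes the mobile distribution wider than
#'   the long-term one.
#' @param passes_mean expected drive-passes per segment (default 8);
#'   realized as 1 + Poisson(passes_mean - 1) so every segment gets at
#'   least one pass.
#' @param per_pass_sd per-pass noise standard deviation.
#' @param temporal_day_sd between-day concentration variation shared
#'   with the reference series.
#' @param temporal_hour_amp amplitude of the within-day (hourly) cycle.
#' @param ref_noise_sd reference-site measurement noise.
#' @param longterm_sites_n number of long-term sites.
#' @param site_offset_distance meters from a site to its road
#'   centerline (about 7 m for facade tubes).
#' @param site_noise_sd noise on the long-term site means (low: long
#'   averaging periods).
#' @return a \code{shift_config} object.
#' @export
shift_config <- function(pollutant = c("no2", "ufp"),
                         on_road_inflation_slope = NULL,
                         daytime_bias = NULL,
                         on_road_excess_sd = NULL,
                         passes_mean = 8,
                         per_pass_sd = NULL,
                         temporal_day_sd = 3,
                         temporal_hour_amp = 2,
                         ref_noise_sd = 0.2,
                         longterm_sites_n = NULL,
                         site_offset_distance = 7,
                         site_noise_sd = NULL) {
  pollutant <- match.arg(pollutant)
  preset <- if (pollutant == "no2") {
    list(slope = 0.06, bias = 0.5, excess_sd = 3.0, per_pass_sd = 6,
         sites = 82, site_noise = 2)
  } else {
    list(slope = 0.24, bias = 1.6, excess_sd = 11, per_pass_sd = 9,
         sites = 17, site_noise = 4)
  }
  stopifnot(passes_mean >= 1, site_offset_distance >= 0)
  structure(list(
    pollutant = toupper(pollutant),
    on_road_inflation_slope = on_road_inflation_slope %||% preset$slope,
    daytime_bias = daytime_bias %||% preset$bias,
    on_road_excess_sd = on_road_excess_sd %||% preset$excess_sd,
    passes_mean = passes_mean,
    per_pass_sd = per_pass_sd %||% preset$per_pass_sd,
    temporal_day_sd = temporal_day_sd,
    temporal_hour_amp = temporal_hour_amp,
    ref_noise_sd = ref_noise_sd,
    longterm_sites_n = longterm_sites_n %||% preset$sites,
    site_offset_distance = site_offset_distance,
    site_noise_sd = site_noise_sd %||% preset$site_noise),
    class = "shift_config")
}

#' Neutral (no-shift) configuration
#'
#' All bias, noise and temporal terms set to zero: mobile aggregates
#' equal the true surface exactly, so source and target are drawn from
#' the same domain.
#' @param pollutant preset for the site count.
#' @param ... overrides passed to \code{\link{shift_config}}.
#' @export
neutral_shift_config <- function(pollutant = "no2", ...) {
  zeroed <- list(on_road_inflation_slope = 0, daytime_bias = 0,
                 on_road_excess_sd = 0, per_pass_sd = 0,
                 temporal_day_sd = 0, temporal_hour_amp = 0,
                 ref_noise_sd = 0, site_noise_sd = 0,
                 site_offset_distance = 0)
  args <- utils::modifyList(zeroed, list(...))
  do.call(shift_config, c(list(pollutant = pollutant), args))
}

# Smoothed-white-noise approximation of a Gaussian random field over
# segment centroids.
smooth_field <- function(cx, cy, range, sd) {
  n <- length(cx)
  z <- stats::rnorm(n)
  W <- exp(-(outer(cx, cx, "-")^2 + outer(cy, cy, "-")^2) / (2 * range^2))
  f <- as.numeric(W %*% z) / sqrt(rowSums(W^2))
  f * sd
}

#' Generate a synthetic scene
#'
#' Builds the grid road network, segments it, attaches covariates and
#' computes the true long-term surface y*.
#'
#' @param config a \code{\link{scene_config}}.
#' @return list with \code{segments} (a \code{road_segments}),
#'   \code{X} (covariate data frame, rownames = segment ids),
#'   \code{directions}, \code{families} (buffer families),
#'   \code{y_star} (named true surface), \code{polylines} and the
#'   config.
#' @export
generate_scene <- function(config = scene_config()) {
  set.seed(derive_seed(config$seed, "scene"))
  k <- config$n_streets
  sp <- config$street_spacing
  ext <- (k - 1) * sp
  polylines <- list()
  major <- character(0)
  for (i in seq_len(k)) {
    idh <- sprintf("H%02d", i)
    idv <- sprintf("V%02d", i)
    polylines[[idh]] <- cbind(c(0, ext), c((i - 1) * sp, (i - 1) * sp))
    polylines[[idv]] <- cbind(c((i - 1) * sp, (i - 1) * sp), c(0, ext))
    if ((i - 1) %% config$major_every == 0) major <- c(major, idh, idv)
  }
  segments <- suppressMessages(
    segment_road_network(polylines, config$segment_length))
  n <- nrow(segments)
  on_major <- segments$road_id %in% major
  # distance from each segment centroid to the nearest major road
  ctr <- cbind(segments$cx, segments$cy)
  dmaj <- dist_points_to_polylines(ctr, polylines[major])
  dmin <- apply(dmaj, 1, min)
  # covariates, scaled to [0, 1]-ish ranges
  traffic <- ifelse(on_major,
                    stats::runif(n, 0.6, 1.0),
                    stats::runif(n, 0.05, 0.45))
  major_road_100 <- pmax(0, 1 - dmin / 100) *
    stats::runif(n, 0.8, 1.2)  # buffer family: major-road proximity
  major_road_500 <- pmax(0, 1 - dmin / 500) * stats::runif(n, 0.8, 1.2)
  population <- plogis(smooth_field(segments$cx, segments$cy,
                                    config$spatial_range, 2))
  industry <- plogis(smooth_field(segments$cx, segments$cy,
                                  config$spatial_range / 2, 2) - 1.5)
  green <- plogis(-smooth_field(segments$cx, segments$cy,
                                config$spatial_range, 2) - 0.5)
  X <- data.frame(traffic_intensity = traffic,
                  major_road_100 = major_road_100,
                  major_road_500 = major_road_500,
                  population = population,
                  industry = industry,
                  green = green)
  rownames(X) <- segments$segment_id
  b <- config$coefficients
  lin <- config$intercept +
    as.matrix(X[names(b)]) %*% b
  y_star <- as.numeric(lin) +
    config$nonlinear_coef * traffic^2 +
    smooth_field(segments$cx, segments$cy, config$spatial_range,
                 config$spatial_sd)
  y_star <- pmax(y_star, 0.1 * config$intercept)
  names(y_star) <- segments$segment_id
  directions <- c(traffic_intensity = "positive",
                  major_road_100 = "positive",
                  major_road_500 = "positive",
                  population = "positive",
                  industry = "positive",
                  green = "negative")
  families <- c(major_road_100 = "major_road",
                major_road_500 = "major_road")
  list(segments = segments, X = X, directions = directions,
       families = families, y_star = y_star, polylines = polylines,
       config = config)
}

# Weekday dates of the campaign window.
campaign_weekdays <- function(from = as.Date("2019-05-27"),
                              to = as.Date("2020-03-13")) {
  days <- seq(from, to, by = "day")
  days[!format(days, "%u") %in% c("6", "7")]
}

#' Generate a mobile monitoring campaign over a scene
#'
#' Per segment, the number of drive-passes is 1 + Poisson(passes_mean -
#' 1). Each pass contributes one observation at the segment centroid
#' (plus a small GPS-like jitter), on a weekday between 08:00 and
#' 22:00: value = y* times the traffic-dependent on-road inflation,
#' plus the daytime bias, plus a day/hour temporal term shared with the
#' reference series, plus per-pass noise, floored at zero. The
#' reference series covers every campaign day-hour.
#'
#' @param scene from \code{\link{generate_scene}}.
#' @param shift a \code{\link{shift_config}}.
#' @param seed integer seed.
#' @return list with \code{observations} (data frame) and
#'   \code{reference} (a \code{\link{reference_series}}).
#' @export
generate_mobile_campaign <- function(scene, shift = shift_config(),
                                     seed = 1) {
  set.seed(derive_seed(seed, "campaign"))
  seg <- scene$segments
  n <- nrow(seg)
  days <- campaign_weekdays()
  day_effect <- stats::rnorm(length(days), 0, shift$temporal_day_sd)
  names(day_effect) <- as.character(days)
  hours <- 8:21
  hour_effect <- shift$temporal_hour_amp *
    sin((hours - 8) / length(hours) * 2 * pi)
  names(hour_effect) <- as.character(hours)

  # persistent per-segment on-road excess (does not average out over
  # passes: it is a property of the location, not of the visit)
  excess <- stats::rnorm(n, 0, shift$on_road_excess_sd)
  n_passes <- 1 + stats::rpois(n, shift$passes_mean - 1)
  tot <- sum(n_passes)
  seg_idx <- rep(seq_len(n), n_passes)
  day_idx <- sample.int(length(days), tot, replace = TRUE)
  hr <- sample(hours, tot, replace = TRUE)
  mins <- sample.int(60, tot, replace = TRUE) - 1
  secs <- sample.int(60, tot, replace = TRUE) - 1
  traffic <- scene$X$traffic_intensity[seg_idx]
  inflation <- 1 + shift$on_road_inflation_slope * traffic
  temporal <- day_effect[day_idx] + hour_effect[as.character(hr)]
  value <- scene$y_star[seg_idx] * inflation + shift$daytime_bias +
    excess[seg_idx] + temporal + stats::rnorm(tot, 0, shift$per_pass_sd)
  value <- pmax(value, 0)
  jitter_r <- if (shift$per_pass_sd > 0) 3 else 0
  obs <- data.frame(
    timestamp = as.POSIXct(paste0(days[day_idx], " ",
                                  sprintf("%02d:%02d:%02d", hr, mins, secs)),
                           tz = "UTC"),
    x = seg$cx[seg_idx] + stats::runif(tot, -jitter_r, jitter_r),
    y = seg$cy[seg_idx] + stats::runif(tot, -jitter_r, jitter_r),
    pollutant = shift$pollutant,
    value = value,
    stringsAsFactors = FALSE)

  ref_grid <- expand.grid(day = seq_along(days), hour = hours)
  ref_base <- stats::median(scene$y_star)
  ref_values <- pmax(ref_base + day_effect[ref_grid$day] +
                       hour_effect[as.character(ref_grid$hour)] +
                       stats::rnorm(nrow(ref_grid), 0, shift$ref_noise_sd), 0)
  ref_ts <- as.POSIXct(paste0(days[ref_grid$day], " ",
                              sprintf("%02d:30:00", ref_grid$hour)),
                       tz = "UTC")
  list(observations = obs,
       reference = reference_series(ref_ts, ref_values))
}

#' Generate the sparse long-term near-road network
#'
#' Places \code{longterm_sites_n} sites at
#' \code{site_offset_distance} meters perpendicular from randomly
#' chosen distinct segments; the site value is the local true surface
#' y* plus low site noise, floored at zero.
#'
#' @param scene from \code{\link{generate_scene}}.
#' @param shift a \code{\link{shift_config}}.
#' @param seed integer seed.
#' @return data frame of sites (\code{site_id}, \code{x}, \code{y},
#'   \code{pollutant}, \code{value}, \code{segment_id} of the home
#'   segment).
#' @export
generate_longterm_network <- function(scene, shift = shift_config(),
                                      seed = 1) {
  set.seed(derive_seed(seed, "longterm"))
  seg <- scene$segments
  n_sites <- shift$longterm_sites_n
  if (n_sites > nrow(seg)) {
    stop("requested ", n_sites, " sites but the scene has only ",
         nrow(seg), " segments")
  }
  pick <- sample.int(nrow(seg), n_sites)
  # perpendicular offset from the segment direction
  dirs <- t(vapply(seg$vertices[pick], function(v) {
    d <- v[nrow(v), ] - v[1, ]
    d / sqrt(sum(d^2))
  }, numeric(2)))
  perp <- cbind(-dirs[, 2], dirs[, 1]) *
    sample(c(-1, 1), n_sites, replace = TRUE)
  value <- pmax(scene$y_star[pick] +
                  stats::rnorm(n_sites, 0, shift$site_noise_sd), 0)
  data.frame(site_id = sprintf("LT%03d", seq_len(n_sites)),
             x = seg$cx[pick] + perp[, 1] * shift$site_offset_distance,
             y = seg$cy[pick] + perp[, 2] * shift$site_offset_distance,
             pollutant = shift$pollutant,
             value = unname(value),
             segment_id = seg$segment_id[pick],
             stringsAsFactors = FALSE)
}

#' Emit a complete fixture bundle on disk
#'
#' Writes the road network (GeoJSON), mobile observations and reference
#' series (CSV), long-term sites (GeoJSON), the per-segment predictor
#' table with declared directions, and the true surface, in exactly the
#' dialects the preparation functions read back.
#'
#' @param dir output directory.
#' @param scene_config,shift_config generator configurations.
#' @param seed integer seed.
#' @return invisibly, the directory path.
#' @export
simulate_bundle <- function(dir, scene_config = lurtransfer::scene_config(),
                            shift_config = lurtransfer::shift_config(),
                            seed = 1) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  scene_config$seed <- as.integer(derive_seed(seed, "bundle_scene"))
  scene <- generate_scene(scene_config)
  camp <- generate_mobile_campaign(scene, shift_config,
                                   seed = derive_seed(seed, "bundle_camp"))
  sites <- generate_longterm_network(scene, shift_config,
                                     seed = derive_seed(seed, "bundle_lt"))
  write_roads_geojson(scene$polylines, file.path(dir, "roads.geojson"))
  write_observations_csv(camp$observations,
                         file.path(dir, "observations.csv"), seed = seed)
  write_reference_csv(camp$reference, file.path(dir, "reference.csv"),
                      seed = seed)
  write_sites_geojson(sites, file.path(dir, "sites.geojson"))
  pred <- cbind(segment_id = rownames(scene$X), scene$X,
                y_star = unname(scene$y_star))
  write_csv_prov(pred, file.path(dir, "predictors.csv"), seed = seed)
  dirs <- data.frame(covariate = names(scene$directions),
                     direction = unname(scene$directions),
                     family = unname(scene$families[names(scene$directions)]),
                     stringsAsFactors = FALSE)
  write_csv_prov(dirs, file.path(dir, "directions.csv"), seed = seed)
  invisible(dir)
}
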