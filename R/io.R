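# File interfaces: CSV for observations / reference / aggregates and a
# minimal GeoJSON dialect (FeatureCollection of LineStrings for roads,
# Points for sites). Every writer prepends a provenance comment header;
# every reader skips '#' comment lines, so outputs round-trip.

provenance_header <- function(seed = NA, config_hash = NA) {
  ver <- as.character(utils::packageVersion("lurtransfer"))
  c(sprintf("# lurtransfer_version=%s", ver),
    sprintf("# seed=%s", seed),
    sprintf("# config_hash=%s", config_hash))
}

write_csv_prov <- function(df, path, seed = NA, config_hash = NA) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(provenance_header(seed, config_hash), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

read_csv_prov <- function(path) {
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

# Content hash of a configuration list (provenance stamping). Path
# fields are excluded so that identical runs in different directories
# produce byte-identical artifacts.
config_hash <- function(config) {
  config <- config[setdiff(names(config), c("dir", "out_dir"))]
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  yaml::write_yaml(config, tmp)
  unname(tools::md5sum(tmp))
}

#' Read / write mobile observation CSV
#'
#' Columns: \code{timestamp} (ISO-8601, UTC), \code{x}, \code{y} (planar
#' meters), \code{pollutant}, \code{value}.
#' @param path file path.
#' @return data frame of observations.
#' @export
read_observations_csv <- function(path) {
  df <- read_csv_prov(path)
  need <- c("timestamp", "x", "y", "pollutant", "value")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("observations file ", path, " lacks column(s): ",
         paste(miss, collapse = ", "))
  }
  bad <- which(!is.finite(df$value) | df$value < 0)
  if (length(bad)) {
    stop("observations file ", path, ": invalid value at row ", bad[1],
         " column 'value'")
  }
  df$timestamp <- as.POSIXct(df$timestamp, tz = "UTC",
                             tryFormats = c("%Y-%m-%dT%H:%M:%S",
                                            "%Y-%m-%d %H:%M:%S"))
  df
}

#' @rdname read_observations_csv
#' @param observations data frame to write.
#' @param seed,config_hash provenance fields stamped into the header.
#' @export
write_observations_csv <- function(observations, path, seed = NA,
                                   config_hash = NA) {
  observations$timestamp <- format(observations$timestamp,
                                   "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  write_csv_prov(observations, path, seed, config_hash)
}

#' Read / write reference-site series CSV
#'
#' Columns: \code{timestamp}, \code{value}.
#' @param path file path.
#' @return a \code{\link{reference_series}}.
#' @export
read_reference_csv <- function(path) {
  df <- read_csv_prov(path)
  df$timestamp <- as.POSIXct(df$timestamp, tz = "UTC",
                             tryFormats = c("%Y-%m-%dT%H:%M:%S",
                                            "%Y-%m-%d %H:%M:%S"))
  reference_series(df$timestamp, df$value)
}

#' @rdname read_reference_csv
#' @param reference a \code{reference_series}.
#' @param seed,config_hash provenance fields.
#' @export
write_reference_csv <- function(reference, path, seed = NA,
                                config_hash = NA) {
  df <- data.frame(
    timestamp = format(reference$timestamps, "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
    value = reference$values)
  write_csv_prov(df, path, seed, config_hash)
}

#' Read / write segment aggregates CSV
#' @param path file path.
#' @return data frame keyed by \code{segment_id}.
#' @export
read_segment_aggregates_csv <- function(path) {
  read_csv_prov(path)
}

#' @rdname read_segment_aggregates_csv
#' @param aggregates data frame from \code{\link{aggregate_segments}}.
#' @param seed,config_hash provenance fields.
#' @export
write_segment_aggregates_csv <- function(aggregates, path, seed = NA,
                                         config_hash = NA) {
  write_csv_prov(aggregates, path, seed, config_hash)
}

#' Read a road network from GeoJSON
#'
#' Expects a FeatureCollection of LineString features, each with an
#' \code{id} property; coordinates are planar meters.
#' @param path GeoJSON file.
#' @return named list of vertex matrices suitable for
#'   \code{\link{segment_road_network}}.
#' @export
read_roads_geojson <- function(path) {
  g <- jsonlite::read_json(path)
  if (!identical(g$type, "FeatureCollection")) {
    stop("roads file ", path, ": expected a GeoJSON FeatureCollection")
  }
  out <- list()
  for (i in seq_along(g$features)) {
    f <- g$features[[i]]
    if (!identical(f$geometry$type, "LineString")) {
      stop("roads file ", path, ": feature ", i, " is not a LineString")
    }
    id <- f$properties$id %||% as.character(i)
    v <- do.call(rbind, lapply(f$geometry$coordinates,
                               function(c) c(c[[1]], c[[2]])))
    out[[as.character(id)]] <- v
  }
  out
}

#' @rdname read_roads_geojson
#' @param polylines named list of vertex matrices.
#' @export
write_roads_geojson <- function(polylines, path) {
  feats <- lapply(names(polylines), function(id) {
    v <- polylines[[id]]
    list(type = "Feature",
         properties = list(id = id),
         geometry = list(type = "LineString",
                         coordinates = lapply(seq_len(nrow(v)),
                                              function(i) c(v[i, 1], v[i, 2]))))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read long-term monitoring sites from GeoJSON
#'
#' Point features with properties \code{site_id}, \code{pollutant},
#' \code{value} (the long-term mean concentration).
#' @param path GeoJSON file.
#' @return data frame with \code{site_id}, \code{x}, \code{y},
#'   \code{pollutant}, \code{value}.
#' @export
read_sites_geojson <- function(path) {
  g <- jsonlite::read_json(path)
  if (!identical(g$type, "FeatureCollection")) {
    stop("sites file ", path, ": expected a GeoJSON FeatureCollection")
  }
  rows <- lapply(seq_along(g$features), function(i) {
    f <- g$features[[i]]
    if (!identical(f$geometry$type, "Point")) {
      stop("sites file ", path, ": feature ", i, " is not a Point")
    }
    val <- f$properties$value
    if (is.null(val) || !is.finite(as.numeric(val)) || as.numeric(val) < 0) {
      stop("sites file ", path, ": feature ", i,
           " has a missing or negative 'value' property")
    }
    data.frame(site_id = as.character(f$properties$site_id %||% i),
               x = f$geometry$coordinates[[1]],
               y = f$geometry$coordinates[[2]],
               pollutant = as.character(f$properties$pollutant %||% NA),
               value = as.numeric(val),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' @rdname read_sites_geojson
#' @param sites data frame of sites.
#' @export
write_sites_geojson <- function(sites, path) {
  feats <- lapply(seq_len(nrow(sites)), function(i) {
    list(type = "Feature",
         properties = list(site_id = sites$site_id[i],
                           pollutant = sites$pollutant[i],
                           value = sites$value[i]),
         geometry = list(type = "Point",
                         coordinates = c(sites$x[i], sites$y[i])))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
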