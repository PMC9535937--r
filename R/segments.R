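#' Divide a road network into fixed-length segments
#'
#' Cuts every polyline of a road network into consecutive pieces of
#' \code{target_length} meters (measured along the line), with one final
#' remainder piece per polyline. A remainder shorter than 20% of
#' \code{target_length} is merged into its predecessor to avoid sliver
#' segments; the merge count is logged. Total length is conserved per
#' polyline.
#'
#' @param polylines named list of vertex matrices (n x 2, planar meters);
#'   names are road identifiers.
#' @param target_length segment length in meters (default 50, the
#'   resolution at which mobile campaigns are conventionally aggregated).
#' @return A \code{road_segments} data frame with columns
#'   \code{segment_id}, \code{road_id}, \code{length}, \code{cx},
#'   \code{cy} and a list column \code{vertices}.
#' @export
segment_road_network <- function(polylines, target_length = 50) {
  stopifnot(target_length > 0, length(polylines) >= 1)
  if (is.null(names(polylines)) || anyDuplicated(names(polylines))) {
    stop("polylines must carry unique names (road identifiers)")
  }
  rows <- list()
  n_merged <- 0L
  for (id in names(polylines)) {
    v <- as.matrix(polylines[[id]])
    if (nrow(v) < 2) stop("polyline '", id, "' has fewer than 2 vertices")
    total <- polyline_length(v)
    if (total <= 0) stop("degenerate (zero-length) polyline: '", id, "'")
    cuts <- seq(0, total, by = target_length)
    if (max(cuts) < total) cuts <- c(cuts, total)
    # merge a final sliver (< 20% of target) into its predecessor
    k <- length(cuts)
    if (k >= 3 && (cuts[k] - cuts[k - 1]) < 0.2 * target_length) {
      cuts <- cuts[-(k - 1)]
      n_merged <- n_merged + 1L
    }
    d <- diff(v)
    seg_len <- sqrt(rowSums(d^2))
    cum <- c(0, cumsum(seg_len))
    for (p in seq_len(length(cuts) - 1)) {
      s0 <- cuts[p]; s1 <- cuts[p + 1]
      inner <- which(cum > s0 + 1e-12 & cum < s1 - 1e-12)
      verts <- rbind(polyline_point_at(v, s0),
                     v[inner, , drop = FALSE],
                     polyline_point_at(v, s1))
      rows[[length(rows) + 1]] <- list(
        segment_id = sprintf("%s-%03d", id, p),
        road_id = id,
        length = s1 - s0,
        vertices = verts)
    }
  }
  log_count(n_merged, "sliver remainder piece(s) merged into predecessor")
  seg <- data.frame(
    segment_id = vapply(rows, `[[`, "", "segment_id"),
    road_id = vapply(rows, `[[`, "", "road_id"),
    length = vapply(rows, `[[`, 0, "length"),
    stringsAsFactors = FALSE)
  seg$vertices <- lapply(rows, `[[`, "vertices")
  ctr <- t(vapply(seg$vertices,
                  function(v) polyline_point_at(v, polyline_length(v) / 2),
                  numeric(2)))
  seg$cx <- ctr[, 1]
  seg$cy <- ctr[, 2]
  if (anyDuplicated(seg$segment_id)) stop("internal: duplicated segment ids")
  class(seg) <- c("road_segments", "data.frame")
  seg
}

#' Snap point observations to their nearest road segment
#'
#' Assigns each observation the segment with minimum Euclidean
#' point-to-polyline distance. Observations farther than
#' \code{max_snap_distance} from every segment stay unassigned
#' (\code{NA}) and are counted. Ties are broken deterministically towards
#' the lexicographically smaller \code{segment_id}.
#'
#' @param observations data frame with numeric \code{x}, \code{y} columns.
#' @param segments a \code{road_segments} object.
#' @param max_snap_distance meters; default 25 (half-width of a wide
#'   carriageway plus GPS error).
#' @return \code{observations} with a \code{segment_id} column and an
#'   attribute \code{n_unassigned}.
#' @export
snap_to_segments <- function(observations, segments, max_snap_distance = 25) {
  stopifnot(nrow(segments) > 0)
  pts <- cbind(observations$x, observations$y)
  # order segments by id so that which.min resolves ties lexicographically
  ord <- order(segments$segment_id)
  polylines <- segments$vertices[ord]
  ids <- segments$segment_id[ord]
  assigned <- rep(NA_character_, nrow(pts))
  chunk <- 2000L
  starts <- seq(1, nrow(pts), by = chunk)
  for (s in starts) {
    idx <- s:min(s + chunk - 1L, nrow(pts))
    D <- dist_points_to_polylines(pts[idx, , drop = FALSE], polylines)
    j <- apply(D, 1, which.min)
    dmin <- D[cbind(seq_along(idx), j)]
    hit <- dmin <= max_snap_distance
    assigned[idx[hit]] <- ids[j[hit]]
  }
  n_miss <- sum(is.na(assigned))
  log_count(n_miss, "observation(s) beyond max_snap_distance left unassigned")
  observations$segment_id <- assigned
  attr(observations, "n_unassigned") <- n_miss
  observations
}
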