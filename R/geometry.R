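# Planar Euclidean geometry on projected (meter) coordinates. All distances
# in this package are Euclidean in a projected CRS supplied by the caller;
# geographic coordinates are out of scope.

# Length of a polyline given as an n x 2 vertex matrix.
polyline_length <- function(v) {
  d <- diff(v)
  sum(sqrt(rowSums(d^2)))
}

# Interpolate the point at arc-length s along polyline v (0 <= s <= length).
polyline_point_at <- function(v, s) {
  d <- diff(v)
  seg_len <- sqrt(rowSums(d^2))
  cum <- c(0, cumsum(seg_len))
  if (s <= 0) return(v[1, ])
  if (s >= cum[length(cum)]) return(v[nrow(v), ])
  i <- findInterval(s, cum, rightmost.closed = TRUE)
  t <- (s - cum[i]) / seg_len[i]
  v[i, ] + t * (v[i + 1, ] - v[i, ])
}

# Minimum distance from points (n x 2) to one line segment a-b.
# Standard clamped-projection formula.
dist_points_to_edge <- function(px, py, ax, ay, bx, by) {
  dx <- bx - ax
  dy <- by - ay
  len2 <- dx * dx + dy * dy
  if (len2 < .Machine$double.eps) {
    return(sqrt((px - ax)^2 + (py - ay)^2))
  }
  t <- ((px - ax) * dx + (py - ay) * dy) / len2
  t <- pmin(pmax(t, 0), 1)
  sqrt((px - (ax + t * dx))^2 + (py - (ay + t * dy))^2)
}

# Minimum distance from each point (n x 2 matrix) to a polyline (m x 2).
dist_points_to_polyline <- function(pts, v) {
  n <- nrow(pts)
  best <- rep(Inf, n)
  for (i in seq_len(nrow(v) - 1)) {
    d <- dist_points_to_edge(pts[, 1], pts[, 2],
                             v[i, 1], v[i, 2], v[i + 1, 1], v[i + 1, 2])
    best <- pmin(best, d)
  }
  best
}

# Distance matrix: points (n x 2) vs a list of polylines. Returns n x k.
dist_points_to_polylines <- function(pts, polylines) {
  out <- matrix(Inf, nrow(pts), length(polylines))
  for (j in seq_along(polylines)) {
    out[, j] <- dist_points_to_polyline(pts, polylines[[j]])
  }
  out
}
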