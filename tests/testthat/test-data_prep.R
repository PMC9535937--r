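test_that("segmentation partitions polylines and conserves length", {
  straight <- list(A = cbind(c(0, 120), c(0, 0)))
  seg <- suppressMessages(segment_road_network(straight, 50))
  expect_equal(seg$length, c(50, 50, 20))
  one <- suppressMessages(
    segment_road_network(list(B = cbind(c(0, 50), c(0, 0))), 50))
  expect_equal(nrow(one), 1)
  expect_equal(one$length, 50)

  set.seed(42)
  polys <- lapply(1:10, function(i) {
    n <- sample(2:6, 1)
    cbind(cumsum(runif(n, 0, 80)), cumsum(runif(n, -40, 40)))
  })
  names(polys) <- sprintf("R%02d", 1:10)
  seg <- suppressMessages(segment_road_network(polys, 50))
  total_in <- sum(vapply(polys, function(v) {
    sum(sqrt(rowSums(diff(v)^2)))
  }, 0))
  expect_equal(sum(seg$length), total_in, tolerance = 1e-6)
  expect_false(anyDuplicated(seg$segment_id) > 0)
  expect_true(all(seg$length > 0))
})

test_that("sliver remainders merge into the predecessor piece", {
  # 105 m at target 50: remainder 5 m < 20% of 50 -> merged into a 55 m piece
  seg <- suppressMessages(
    segment_road_network(list(A = cbind(c(0, 105), c(0, 0))), 50))
  expect_equal(seg$length, c(50, 55))
})

test_that("degenerate polylines are rejected with their identifier", {
  bad <- list(OK = cbind(c(0, 10), c(0, 0)), ZZ = cbind(c(1, 1), c(2, 2)))
  expect_error(segment_road_network(bad, 50), "ZZ")
})

test_that("snapping matches the brute-force nearest-segment oracle", {
  set.seed(7)
  polys <- list()
  for (i in 1:5) {
    polys[[sprintf("R%d", i)]] <-
      cbind(c(0, 400), c((i - 1) * 100, (i - 1) * 100))
  }
  seg <- suppressMessages(segment_road_network(polys, 50))
  pts <- cbind(runif(200, -20, 420), runif(200, -40, 440))
  obs <- data.frame(x = pts[, 1], y = pts[, 2])
  snapped <- suppressMessages(snap_to_segments(obs, seg, 30))
  expect_identical(snapped$segment_id, oracle_snap(pts, seg, 30))
  # idempotence: snapping the snapped set changes nothing
  again <- suppressMessages(snap_to_segments(snapped, seg, 30))
  expect_identical(again$segment_id, snapped$segment_id)
})

test_that("snapping handles nearest, unassigned and tie cases", {
  seg <- suppressMessages(segment_road_network(
    list(A = cbind(c(0, 50), c(0, 0)), B = cbind(c(0, 50), c(40, 40))), 50))
  obs <- data.frame(x = c(10, 10, 10), y = c(1, 20, 150))
  snapped <- suppressMessages(snap_to_segments(obs, seg, 25))
  expect_equal(snapped$segment_id[1], "A-001")   # 1 m vs 39 m
  expect_equal(snapped$segment_id[2], "A-001")   # exact tie -> smaller id
  expect_true(is.na(snapped$segment_id[3]))      # beyond max distance
  expect_equal(attr(snapped, "n_unassigned"), 1)
})

test_that("temporal correction applies the additive and ratio formulas", {
  ref <- reference_series(
    as.POSIXct(c("2019-06-03 09:30:00", "2019-06-03 10:30:00"), tz = "UTC"),
    c(25, 15))  # campaign mean 20
  obs <- data.frame(
    timestamp = as.POSIXct("2019-06-03 09:10:00", tz = "UTC"),
    value = 30)
  expect_equal(temporal_correct(obs, ref, "additive")$value, 25)
  expect_equal(temporal_correct(obs, ref, "multiplicative")$value, 24)
})

test_that("a constant reference series makes both corrections no-ops", {
  ts <- seq(as.POSIXct("2019-06-03 08:00:00", tz = "UTC"),
            by = 3600, length.out = 10)
  ref <- reference_series(ts, rep(21.5, 10))
  obs <- data.frame(timestamp = ts[3:6] + 120, value = c(10, 22.4, 35, 7))
  expect_equal(temporal_correct(obs, ref, "additive")$value, obs$value)
  expect_equal(temporal_correct(obs, ref, "multiplicative")$value, obs$value)
})

test_that("observations without reference coverage are dropped and counted", {
  ref <- reference_series(as.POSIXct("2019-06-03 09:30:00", tz = "UTC"), 20)
  obs <- data.frame(
    timestamp = as.POSIXct(c("2019-06-03 09:10:00", "2019-06-04 09:10:00"),
                           tz = "UTC"),
    value = c(30, 30))
  out <- suppressMessages(temporal_correct(obs, ref, "additive"))
  expect_equal(nrow(out), 1)
  expect_equal(attr(out, "n_dropped"), 1)
})

test_that("aggregation reproduces an independent group-by computation", {
  set.seed(11)
  n <- 300
  obs <- data.frame(
    timestamp = as.POSIXct("2019-06-03", tz = "UTC") +
      sample(0:(86400 * 9), n, replace = TRUE),
    segment_id = sample(sprintf("S%02d", 1:12), n, replace = TRUE),
    pollutant = sample(c("NO2", "UFP"), n, replace = TRUE),
    value = runif(n, 5, 60))
  agg <- aggregate_segments(obs)
  # independent oracle: split-based recomputation
  key <- paste(obs$segment_id, obs$pollutant)
  for (k in unique(key)) {
    rows <- obs[key == k, ]
    got <- agg[agg$segment_id == rows$segment_id[1] &
                 agg$pollutant == rows$pollutant[1], ]
    expect_equal(got$mean_conc, mean(rows$value))
    expect_equal(got$n_obs, nrow(rows))
    expect_equal(got$n_drive_passes,
                 length(unique(format(rows$timestamp, "%Y-%m-%d"))))
    expect_true(got$mean_conc >= min(rows$value) &&
                  got$mean_conc <= max(rows$value))
    expect_true(got$n_drive_passes <= got$n_obs)
  }
})

test_that("site matching equals a brute-force distance filter", {
  set.seed(3)
  polys <- list(A = cbind(c(0, 300), c(0, 0)),
                B = cbind(c(0, 300), c(60, 60)))
  seg <- suppressMessages(segment_road_network(polys, 50))
  sites <- data.frame(site_id = sprintf("s%d", 1:30),
                      x = runif(30, -20, 320), y = runif(30, -40, 100),
                      pollutant = "NO2", value = runif(30, 10, 40))
  matched <- suppressMessages(match_sites_to_segments(sites, seg, 30))
  for (i in seq_len(nrow(sites))) {
    d <- vapply(seq_len(nrow(seg)), function(j) {
      oracle_point_polyline_dist(c(sites$x[i], sites$y[i]),
                                 seg$vertices[[j]])
    }, 0)
    expect_setequal(matched$matched_segment_ids[[i]],
                    seg$segment_id[d <= 30])
  }
  expect_identical(matched$unmatched,
                   lengths(matched$matched_segment_ids) == 0)
})

test_that("a facade-distance site matches and a 31 m site is flagged", {
  seg <- suppressMessages(
    segment_road_network(list(A = cbind(c(0, 50), c(0, 0))), 50))
  sites <- data.frame(site_id = c("near", "far"), x = c(25, 25),
                      y = c(7, 31), pollutant = "NO2", value = c(26, 26))
  m <- suppressMessages(match_sites_to_segments(sites, seg, 30))
  expect_equal(m$matched_segment_ids[[1]], "A-001")
  expect_equal(length(m$matched_segment_ids[[2]]), 0)
  expect_true(m$unmatched[2])
})
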