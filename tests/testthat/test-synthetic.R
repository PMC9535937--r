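test_that("scenes are reproducible and respect the declared structure", {
  a <- generate_scene(scene_config(n_streets = 4, seed = 9))
  b <- generate_scene(scene_config(n_streets = 4, seed = 9))
  expect_identical(a$X, b$X)
  expect_identical(a$y_star, b$y_star)
  expect_true(all(a$y_star > 0))
  expect_equal(nrow(a$X), nrow(a$segments))
  expect_setequal(names(a$directions), names(a$X))
  # traffic is the dominant declared positive driver of the surface
  expect_gt(cor(a$X$traffic_intensity, a$y_star), 0)
})

test_that("the surface correlates with traffic at the configured effect", {
  # empirical traffic correlation is stable across seeds
  cors <- vapply(1:5, function(s) {
    sc <- generate_scene(scene_config(n_streets = 5, seed = s))
    cor(sc$X$traffic_intensity, sc$y_star)
  }, 0)
  expect_true(all(abs(cors - mean(cors)) < 0.1))
  expect_true(all(cors > 0.5))
})

test_that("a noise-free linear scene lets SLR recover the coefficients", {
  sc <- scene_config(n_streets = 4, nonlinear_coef = 0, spatial_sd = 0,
                     seed = 3)
  scene <- generate_scene(sc)
  # no family cap here: the true surface uses both buffer variants
  m <- suppressMessages(fit_slr(scene$X, unname(scene$y_star),
                                scene$directions,
                                gain_threshold = 1e-6, p_remove = 1))
  for (v in names(m$coefficients)) {
    expect_equal(unname(m$coefficients[v]),
                 unname(sc$coefficients[v]), tolerance = 1e-6)
  }
  expect_equal(m$adjusted_r2, 1, tolerance = 1e-9)
})

test_that("a neutral campaign reproduces the true surface exactly", {
  scene <- generate_scene(scene_config(n_streets = 4, seed = 5))
  camp <- generate_mobile_campaign(scene, neutral_shift_config(), seed = 6)
  obs <- temporal_correct(camp$observations, camp$reference,
                          "multiplicative")
  obs <- suppressMessages(snap_to_segments(obs, scene$segments))
  expect_false(anyNA(obs$segment_id))
  agg <- aggregate_segments(obs)
  expect_equal(agg$mean_conc[match(names(scene$y_star), agg$segment_id)],
               unname(scene$y_star), tolerance = 1e-9)
})

test_that("drive-pass counts follow the shifted Poisson model", {
  scene <- generate_scene(scene_config(n_streets = 12, seed = 7))
  expect_gte(nrow(scene$segments), 1000)
  camp <- generate_mobile_campaign(scene, neutral_shift_config(), seed = 8)
  obs <- suppressMessages(snap_to_segments(camp$observations,
                                           scene$segments))
  agg <- aggregate_segments(obs[!is.na(obs$segment_id), ])
  expect_true(all(agg$n_drive_passes >= 1))
  expect_lt(abs(mean(agg$n_drive_passes) - 8), 0.5)
  # weekday daytime sampling window
  h <- as.integer(format(camp$observations$timestamp, "%H"))
  expect_true(all(h >= 8 & h <= 21))
  wd <- format(camp$observations$timestamp, "%u")
  expect_false(any(wd %in% c("6", "7")))
})

test_that("noisy aggregates converge to the surface as passes grow", {
  scene <- generate_scene(scene_config(n_streets = 4, seed = 10))
  sh <- neutral_shift_config(passes_mean = 200, per_pass_sd = 6)
  camp <- generate_mobile_campaign(scene, sh, seed = 11)
  obs <- suppressMessages(snap_to_segments(camp$observations,
                                           scene$segments))
  agg <- aggregate_segments(obs[!is.na(obs$segment_id), ])
  y <- scene$y_star[agg$segment_id]
  expect_lt(mean(abs(agg$mean_conc - y)), 0.02 * mean(y))
})

test_that("default shifts reproduce the campaign's published signatures", {
  for (pol in c("no2", "ufp")) {
    up <- 0
    for (seed in 1:10) {
      scene <- generate_scene(scene_config(n_streets = 4, seed = seed))
      sh <- shift_config(pol)
      camp <- generate_mobile_campaign(scene, sh, seed = seed + 50)
      obs <- suppressMessages(snap_to_segments(camp$observations,
                                               scene$segments))
      agg <- aggregate_segments(obs[!is.na(obs$segment_id), ])
      sites <- generate_longterm_network(
        scene, shift_config(pol, longterm_sites_n = 40), seed = seed + 60)
      if (mean(agg$mean_conc) > mean(sites$value)) up <- up + 1
      if (seed == 1) {
        # mobile distribution wider than the long-term one
        expect_gt(var(agg$mean_conc) / var(sites$value), 1)
      }
    }
    expect_equal(up, 10)
  }
})

test_that("long-term sites sit at the configured offset from their road", {
  scene <- generate_scene(scene_config(n_streets = 4, seed = 12))
  sh <- shift_config("ufp", site_offset_distance = 7)
  sites <- generate_longterm_network(scene, sh, seed = 13)
  expect_equal(nrow(sites), 17)
  d <- vapply(seq_len(nrow(sites)), function(i) {
    min(vapply(scene$segments$vertices, function(v) {
      oracle_point_polyline_dist(c(sites$x[i], sites$y[i]), v)
    }, 0))
  }, 0)
  expect_true(all(d <= 7 + 1e-6))
  expect_gt(mean(d), 3)  # mostly near the offset, except at crossings
  # exact surface values with zero site noise and offset
  s0 <- generate_longterm_network(
    scene, neutral_shift_config(longterm_sites_n = 10), seed = 14)
  expect_equal(s0$value, unname(scene$y_star[s0$segment_id]))
  expect_error(
    generate_longterm_network(
      scene, shift_config("no2", longterm_sites_n = 10000), seed = 1),
    "segments")
})
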