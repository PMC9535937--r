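test_that("metrics reproduce hand arithmetic and identities", {
  obs <- c(10, 20, 30)
  pred <- c(20, 20, 20)
  expect_equal(nmae(pred, obs), (10 + 0 + 10) / 3 / 20)
  expect_equal(nrmse(pred, obs), sqrt(200 / 3) / 20)
  expect_equal(nmae(obs, obs), 0)
  expect_equal(nrmse(obs, obs), 0)
  expect_equal(r2_pearson(obs, obs), 1)
  # affine invariance of squared Pearson
  expect_equal(r2_pearson(2 * obs + 5, obs), 1)
  expect_error(nmae(c(1, 2), c(0, 0)), "positive")
  expect_error(r2_pearson(c(1, 1), c(2, 3)), "variance")
})

test_that("metrics are invariant to permuting the pairs", {
  set.seed(1)
  obs <- runif(40, 10, 50)
  pred <- obs + rnorm(40, 0, 3)
  p <- sample(40)
  expect_equal(nmae(pred[p], obs[p]), nmae(pred, obs))
  expect_equal(nrmse(pred[p], obs[p]), nrmse(pred, obs))
  expect_equal(r2_pearson(pred[p], obs[p]), r2_pearson(pred, obs))
})

test_that("nRMSE is never smaller than nMAE", {
  for (seed in 1:20) {
    set.seed(seed)
    obs <- runif(15, 5, 50)
    pred <- obs + rnorm(15, 0, 5)
    expect_gte(nrmse(pred, obs), nmae(pred, obs) - 1e-12)
  }
})

test_that("improvement percentages follow the median formula", {
  expect_equal(improvement_percentage(0.13, 0.29), -55.2)
  expect_equal(improvement_percentage(0.19, 0.26), -26.9)
  expect_equal(improvement_percentage(0.4, 0.4), 0)
  expect_error(improvement_percentage(0.1, 0), "positive")
})

test_that("site aggregation equals a brute-force filter-and-mean", {
  set.seed(2)
  seg_pred <- runif(30, 10, 40)
  names(seg_pred) <- sprintf("S%02d", 1:30)
  sites <- data.frame(site_id = sprintf("L%d", 1:8))
  sites$matched_segment_ids <- lapply(1:8, function(i) {
    sample(names(seg_pred), sample(0:4, 1))
  })
  has <- lengths(sites$matched_segment_ids) > 0
  got <- if (all(has)) site_predictions(seg_pred, sites) else
    suppressWarnings(site_predictions(seg_pred, sites))
  expect_equal(length(got), sum(has))
  for (i in which(has)) {
    expect_equal(unname(got[sites$site_id[i]]),
                 mean(seg_pred[sites$matched_segment_ids[[i]]]))
  }
  # one matched segment passes through; two average
  s1 <- data.frame(site_id = "a")
  s1$matched_segment_ids <- list(c("S01"))
  expect_equal(unname(site_predictions(seg_pred, s1)),
               unname(seg_pred["S01"]))
  s2 <- data.frame(site_id = "b")
  s2$matched_segment_ids <- list(c("S01", "S02"))
  expect_equal(unname(site_predictions(seg_pred, s2)),
               mean(seg_pred[c("S01", "S02")]))
})

test_that("the protocol is deterministic and splits 17 sites as 9/8", {
  prep <- make_prepared_scene(101, shift_config("ufp"), n_streets = 4)
  expect_equal(nrow(prep$sites), 17)
  r1 <- suppressMessages(run_protocol(
    prep, models = c("rf_lur", "prior_rf"), n_iterations = 2, seed = 77,
    rf_config = rf_config(n_trees = 50),
    rulsif_config = rulsif_config(n_centers = 17)))
  r2 <- suppressMessages(run_protocol(
    prep, models = c("rf_lur", "prior_rf"), n_iterations = 2, seed = 77,
    rf_config = rf_config(n_trees = 50),
    rulsif_config = rulsif_config(n_centers = 17)))
  expect_identical(r1$per_iteration, r2$per_iteration)
  expect_identical(r1$summary, r2$summary)
  # 50/50 site split of an odd count: ceiling(n/2) train
  expect_equal(ceiling(17 / 2), 9)
  expect_equal(17 - ceiling(17 / 2), 8)
})

test_that("the report covers every model, metric and iteration", {
  prep <- make_prepared_scene(102, shift_config("ufp"), n_streets = 4)
  rep <- suppressMessages(run_protocol(
    prep,
    models = c("slr", "rf_lur", "prior_rf", "tradaboost"),
    n_iterations = 2, seed = 5,
    rf_config = rf_config(n_trees = 50),
    rulsif_config = rulsif_config(n_centers = 17),
    slr_directions = prep$scene$directions,
    slr_families = prep$scene$families,
    tradaboost = list(S = 4, n_estimators = 8, cv_folds = 3)))
  expect_equal(nrow(rep$per_iteration), 4 * 2)
  expect_equal(nrow(rep$summary), 4 * 3)
  expect_true(all(c("nmae", "nrmse", "r2") %in% rep$summary$metric))
  # summary invariants
  expect_true(all(rep$summary$ci_lower <= rep$summary$mean + 1e-12))
  expect_true(all(rep$summary$mean <= rep$summary$ci_upper + 1e-12))
  expect_true(all(rep$per_iteration$nmae >= 0))
  expect_true(all(rep$per_iteration$r2 >= 0 & rep$per_iteration$r2 <= 1))
  # improvements exist for each transfer/baseline/metric combination
  expect_equal(nrow(rep$improvements), 2 * 2 * 3)
  # medians reproduce the improvement table
  med <- function(m, k) {
    rep$summary$median[rep$summary$model == m & rep$summary$metric == k]
  }
  row <- rep$improvements[rep$improvements$transfer == "prior_rf" &
                            rep$improvements$baseline == "rf_lur" &
                            rep$improvements$metric == "nmae", ]
  expect_equal(row$improvement_pct,
               improvement_percentage(med("prior_rf", "nmae"),
                                      med("rf_lur", "nmae")))
})

test_that("percentile CIs cover the mean under a null resampling check", {
  set.seed(9)
  cover <- 0
  for (i in 1:200) {
    v <- rnorm(20)
    ci <- quantile(v, c(0.025, 0.975))
    if (mean(v) >= ci[1] && mean(v) <= ci[2]) cover <- cover + 1
  }
  expect_gte(cover / 200, 0.95)
})
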