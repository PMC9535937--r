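# Two-stage TrAdaBoost.R2 and Prior_RF behaviour on controlled data.

make_domains <- function(seed, n_s = 60, n_t = 12, shift = 0) {
  set.seed(seed)
  f <- function(X) 20 + 6 * X$x1 - 3 * X$x2
  Xs <- data.frame(x1 = runif(n_s), x2 = runif(n_s))
  Xt <- data.frame(x1 = runif(n_t), x2 = runif(n_t))
  list(Xs = Xs, ys = f(Xs) + shift + rnorm(n_s, 0, 0.7),
       Xt = Xt, yt = f(Xt) + rnorm(n_t, 0, 0.4))
}

test_that("an empty source reduces to plain AdaBoost.R2 on the target", {
  d <- make_domains(1)
  tb <- suppressMessages(fit_two_stage_tradaboost_r2(
    d$Xt[0, ], numeric(0), d$Xt, d$yt, S = 4, n_estimators = 10,
    cv_folds = 3, seed = 5))
  ada <- fit_adaboost_r2(d$Xt, d$yt, n_estimators = 10)
  newX <- data.frame(x1 = runif(20), x2 = runif(20))
  expect_equal(suppressMessages(predict(tb, newX)), predict(ada, newX),
               tolerance = 1e-10)
})

test_that("the stage-1 schedule runs from the merged fraction to one", {
  d <- make_domains(2)
  tb <- suppressMessages(fit_two_stage_tradaboost_r2(
    d$Xs, d$ys, d$Xt, d$yt, S = 6, n_estimators = 8, cv_folds = 3,
    seed = 3))
  n_s <- nrow(d$Xs); n_t <- nrow(d$Xt)
  expect_equal(tb$schedule[1], n_t / (n_s + n_t))
  expect_equal(tb$schedule[6], 1)
  # realized target fraction follows the schedule (up to the clamp for
  # perfectly fitting source instances) and never decreases
  expect_true(all(diff(tb$realized_fractions) >= -1e-9))
  expect_equal(tb$realized_fractions[1], n_t / (n_s + n_t),
               tolerance = 1e-9)
  expect_true(all(abs(tb$realized_fractions - tb$schedule) < 1e-4 |
                    tb$realized_fractions < tb$schedule))
  # per-step starting weights are probability vectors
  expect_true(all(abs(rowSums(tb$weight_history) - 1) < 1e-9))
  expect_true(all(tb$weight_history >= 0))
  expect_true(tb$chosen_step >= 0 && tb$chosen_step <= 5)
})

test_that("step selection equals exhaustive target-CV evaluation", {
  d <- make_domains(3, n_s = 30, n_t = 10)
  S <- 4
  tb <- suppressMessages(fit_two_stage_tradaboost_r2(
    d$Xs, d$ys, d$Xt, d$yt, S = S, n_estimators = 8, cv_folds = 5,
    seed = 7))
  # independent replay: for each stored step's starting weights,
  # recompute the fold errors directly and compare the selected step
  X_all <- rbind(d$Xs, d$Xt)
  y_all <- c(d$ys, d$yt)
  is_t <- c(rep(FALSE, 30), rep(TRUE, 10))
  cv <- vapply(seq_len(S), function(t) {
    w <- tb$weight_history[t, ]
    errs <- vapply(seq_len(max(tb$folds)), function(f) {
      hold <- which(is_t)[tb$folds == f]
      keep <- setdiff(seq_along(y_all), hold)
      m <- fit_adaboost_r2(X_all[keep, ], y_all[keep], weights = w[keep],
                           n_estimators = 8, frozen_mask = !is_t[keep])
      mean((predict(m, X_all[hold, ]) - y_all[hold])^2)
    }, 0)
    mean(errs)
  }, 0)
  expect_equal(tb$cv_errors, cv, tolerance = 1e-10)
  expect_equal(tb$chosen_step, which.min(cv) - 1L)
})

test_that("tradaboost is reproducible from its seed", {
  d <- make_domains(4)
  a <- suppressMessages(fit_two_stage_tradaboost_r2(
    d$Xs, d$ys, d$Xt, d$yt, S = 4, n_estimators = 8, cv_folds = 3,
    seed = 11))
  b <- suppressMessages(fit_two_stage_tradaboost_r2(
    d$Xs, d$ys, d$Xt, d$yt, S = 4, n_estimators = 8, cv_folds = 3,
    seed = 11))
  newX <- data.frame(x1 = runif(10), x2 = runif(10))
  expect_identical(suppressMessages(predict(a, newX)),
                   suppressMessages(predict(b, newX)))
  expect_identical(a$chosen_step, b$chosen_step)
})

test_that("prior_rf with overridden unit weights equals the plain forest", {
  d <- make_domains(5, n_s = 120)
  cfg <- rf_config(n_trees = 80, seed = 2)
  pr <- suppressMessages(fit_prior_rf(d$Xs, d$ys, d$yt, cfg,
                                      rulsif_config(seed = 2),
                                      override_weights = rep(1, 120)))
  rf <- fit_rf(d$Xs, d$ys, cfg)
  newX <- data.frame(x1 = runif(30), x2 = runif(30))
  expect_identical(suppressMessages(predict(pr, newX)), predict(rf, newX))
})

test_that("prior_rf matches the plain forest when domains coincide", {
  # identically distributed source and target: the ratio is ~1 and the
  # reweighted forest should track the unweighted one closely
  diffs <- vapply(1:5, function(seed) {
    d <- make_domains(seed + 10, n_s = 500, n_t = 80)
    cfg <- rf_config(n_trees = 150, seed = seed)
    rf <- fit_rf(d$Xs, d$ys, cfg)
    pr <- suppressMessages(fit_prior_rf(d$Xs, d$ys, d$yt, cfg,
                                        rulsif_config(seed = seed)))
    newX <- data.frame(x1 = runif(200), x2 = runif(200))
    truth <- 20 + 6 * newX$x1 - 3 * newX$x2
    abs(nmae(suppressMessages(predict(pr, newX)), truth) -
          nmae(predict(rf, newX), truth))
  }, 0)
  expect_lt(max(diffs), 0.02)
})

test_that("prior_rf beats the plain forest under a positive source bias", {
  # on-road style inflation: source responses inflated ~20%
  wins <- 0
  for (seed in 1:5) {
    d <- make_domains(seed + 20, n_s = 400, n_t = 60, shift = 0)
    ys_biased <- d$ys * 1.2
    cfg <- rf_config(n_trees = 150, seed = seed)
    rf <- fit_rf(d$Xs, ys_biased, cfg)
    pr <- suppressMessages(fit_prior_rf(d$Xs, ys_biased, d$yt, cfg,
                                        rulsif_config(seed = seed)))
    newX <- data.frame(x1 = runif(150), x2 = runif(150))
    truth <- 20 + 6 * newX$x1 - 3 * newX$x2
    if (nmae(suppressMessages(predict(pr, newX)), truth) <
          nmae(predict(rf, newX), truth)) {
      wins <- wins + 1
    }
  }
  expect_gte(wins, 4)
})

test_that("single-learner ensembles predict with that learner", {
  X <- data.frame(x = 1:6)
  y <- c(2, 4, 6, 8, 10, 12)
  m <- fit_adaboost_r2(X, y, n_estimators = 1, max_depth = 4)
  expect_length(m$learners, 1)
  expect_equal(predict(m, X), unname(predict(m$learners[[1]], X)))
})
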