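# Instance-based transfer-learning LUR models. Source instances are
# mobile segment aggregates; target instances are long-term near-road
# observations. Prior_RF reweights the random forest's risk function by
# the RuLSIF-estimated target/source density ratio of the response;
# TrAdaBoost merges both instance sets and adapts instance weights by
# boosting, de-emphasizing source instances on a fixed schedule.

weighted_median <- function(values, weights) {
  ord <- order(values)
  v <- values[ord]
  w <- weights[ord]
  cw <- cumsum(w)
  v[which(cw >= 0.5 * sum(w))[1]]
}

fit_weighted_tree <- function(X, y, w, max_depth = 6) {
  dat <- cbind(as.data.frame(X), .y = y)
  # scale weights to pseudo-counts; rpart treats them as case weights
  rpart::rpart(.y ~ ., data = dat, weights = w * length(y),
               method = "anova",
               control = rpart::rpart.control(maxdepth = max_depth, cp = 0,
                                              minsplit = 5, minbucket = 2,
                                              xval = 0))
}

#' AdaBoost.R2 regression boosting
#'
#' Classic AdaBoost.R2 with depth-capped regression trees as base
#' learners. Per iteration: fit a weighted tree; compute adjusted
#' errors \code{e_i = L(|y_i - f(x_i)| / D)} where \code{D} is the
#' maximum residual and L the chosen loss (linear, square or
#' exponential); the weighted error \code{eps = sum(w_i e_i)} stops
#' boosting when it reaches 0.5; otherwise \code{beta = eps/(1-eps)}
#' and \code{w_i <- w_i * beta^(1-e_i)} for unfrozen instances,
#' followed by renormalization. Prediction is the weighted median of
#' the learners with learner weights \code{log(1/beta)}.
#'
#' @param X covariate data frame.
#' @param y responses.
#' @param weights initial instance weights (default uniform); they are
#'   normalized to sum 1.
#' @param n_estimators maximum boosting iterations (default 30).
#' @param loss "linear", "square" or "exponential".
#' @param frozen_mask logical per instance; frozen instances keep their
#'   (renormalized) weights across iterations.
#' @param max_depth base-tree depth cap (default 6).
#' @return an \code{adaboost_r2} model with learners, learner weights
#'   and the per-iteration \code{weight_history} (rows sum to 1).
#' @export
fit_adaboost_r2 <- function(X, y, weights = NULL, n_estimators = 30,
                            loss = c("linear", "square", "exponential"),
                            frozen_mask = NULL, max_depth = 6) {
  loss <- match.arg(loss)
  X <- as.data.frame(X)
  n <- nrow(X)
  stopifnot(length(y) == n, n >= 2)
  w <- weights %||% rep(1, n)
  stopifnot(all(w >= 0), sum(w) > 0)
  w <- w / sum(w)
  frozen <- frozen_mask %||% rep(FALSE, n)
  stopifnot(length(frozen) == n)
  learners <- list()
  betas <- numeric(0)
  history <- list()
  for (m in seq_len(n_estimators)) {
    tree <- fit_weighted_tree(X, y, w, max_depth)
    pred <- stats::predict(tree, X)
    resid <- abs(y - pred)
    D <- max(resid)
    if (D < 1e-12) {  # perfect fit: single-learner stop
      learners[[length(learners) + 1]] <- tree
      betas <- c(betas, 1e-10)
      history[[length(history) + 1]] <- w
      break
    }
    e <- switch(loss,
                linear = resid / D,
                square = (resid / D)^2,
                exponential = 1 - exp(-resid / D))
    eps <- sum(w * e)
    if (eps >= 0.5) {
      if (!length(learners)) {  # keep one learner rather than none
        learners[[1]] <- tree
        betas <- 1
        history[[1]] <- w
      }
      break
    }
    beta <- eps / (1 - eps)
    learners[[length(learners) + 1]] <- tree
    betas <- c(betas, beta)
    w[!frozen] <- w[!frozen] * beta^(1 - e[!frozen])
    w <- w / sum(w)
    history[[length(history) + 1]] <- w
  }
  structure(list(learners = learners,
                 learner_weights = log(1 / betas),
                 weight_history = do.call(rbind, history),
                 final_weights = w, loss = loss, max_depth = max_depth),
            class = "adaboost_r2")
}

#' @export
predict.adaboost_r2 <- function(object, newdata, ...) {
  newdata <- as.data.frame(newdata)
  P <- vapply(object$learners, function(l) stats::predict(l, newdata),
              numeric(nrow(newdata)))
  P <- matrix(P, nrow = nrow(newdata))
  apply(P, 1, weighted_median, weights = object$learner_weights)
}

#' Prior_RF: density-ratio-reweighted random forest
#'
#' Fits RuLSIF on the long-term (target) versus mobile (source)
#' concentration distributions, evaluates the fitted ratio at the
#' source responses, normalizes the floored weights to mean 1 and feeds
#' them into the conventional random forest as instance weights. The
#' forest hyperparameters are kept identical to the baseline RF_LUR's
#' chosen configuration so that the two models differ only in the risk
#' reweighting.
#'
#' @param source_X mobile segment covariates.
#' @param source_y mobile segment mean concentrations.
#' @param target_y long-term site concentrations.
#' @param rf_config the baseline RF_LUR's chosen \code{\link{rf_config}}.
#' @param rulsif_config a \code{\link{rulsif_config}}.
#' @param weight_floor minimum instance weight before normalization.
#' @param ratio_on "response" (default: ratio over the concentration
#'   axis) or "covariates" (covariate-shift variant over the predictor
#'   space).
#' @param target_X target covariates; only needed for the
#'   covariate-shift variant.
#' @param override_weights optional fixed instance weights used instead
#'   of the fitted ratio (diagnostic; unit weights reproduce the plain
#'   forest exactly).
#' @return a \code{transfer_ensemble} (method \code{prior_rf}).
#' @export
fit_prior_rf <- function(source_X, source_y, target_y,
                         rf_config = rf_config(),
                         rulsif_config = rulsif_config(),
                         weight_floor = 1e-3,
                         ratio_on = c("response", "covariates"),
                         target_X = NULL, override_weights = NULL) {
  ratio_on <- match.arg(ratio_on)
  stopifnot(length(source_y) >= 1, length(target_y) >= 1)
  if (!is.null(override_weights)) {
    ratio <- NULL
    w <- override_weights
  } else if (ratio_on == "response") {
    ratio <- fit_rulsif(target_y, source_y, rulsif_config)
    w <- evaluate_ratio(ratio, source_y, weight_floor)
  } else {
    if (is.null(target_X)) stop("covariate-shift variant needs target_X")
    ratio <- fit_rulsif(as.matrix(target_X), as.matrix(source_X),
                        rulsif_config)
    w <- evaluate_ratio(ratio, as.matrix(source_X), weight_floor)
  }
  w <- w / mean(w)  # scale-free: normalized to mean 1 before use
  forest <- fit_rf(source_X, source_y, rf_config, sample_weights = w)
  structure(list(method = "prior_rf", forest = forest, ratio_model = ratio,
                 instance_weights = w, rf_config = rf_config,
                 seed = rf_config$seed),
            class = "transfer_ensemble")
}

#' Two-stage TrAdaBoost.R2 transfer boosting
#'
#' Merges source (mobile) and target (long-term) instances with equal
#' initial weights, then alternates the two stages over steps
#' t = 0..S-1:
#' \itemize{
#'   \item Stage 2 (per step): AdaBoost.R2 runs on the merged set with
#'     all source weights frozen — only target-instance weights adapt
#'     inside the boosting loop. The step's model is scored by k-fold
#'     cross-validated squared error on the target instances only.
#'   \item Stage 1 (between steps): source instances that the current
#'     step's model fits poorly — i.e. those most different from the
#'     target-calibrated fit — are de-emphasized by the multiplicative
#'     update \code{w_i <- w_i * beta^e_i} (adjusted errors
#'     \code{e_i} in [0,1]), with \code{beta} found by bisection so
#'     that the total target-weight fraction follows the schedule
#'     \code{n_t/(n_s+n_t) + t/(S-1) * (1 - n_t/(n_s+n_t))}. When the
#'     schedule's fraction is unreachable (perfectly fitting source
#'     instances keep weight at any beta), the nearest achievable
#'     fraction is used and logged.
#' }
#' The step with minimal target CV error is returned.
#'
#' @param source_X,source_y mobile instances (may be empty).
#' @param target_X,target_y long-term instances.
#' @param S number of steps of the de-emphasis schedule (default 10).
#' @param n_estimators boosting iterations per step (default 30).
#' @param cv_folds folds for step selection; reduced automatically when
#'   the target set is smaller.
#' @param loss AdaBoost.R2 loss function.
#' @param max_depth base-tree depth cap.
#' @param seed integer seed (fold assignment).
#' @return a \code{transfer_ensemble} (method \code{tradaboost}) with
#'   the chosen step and its model, per-step CV errors, the stage-1
#'   schedule, the realized target-weight fraction per step and the
#'   per-step starting weights (\code{weight_history}, rows sum to 1).
#' @export
fit_two_stage_tradaboost_r2 <- function(source_X, source_y,
                                        target_X, target_y,
                                        S = 10, n_estimators = 30,
                                        cv_folds = 5,
                                        loss = "linear", max_depth = 6,
                                        seed = 1) {
  stopifnot(S >= 2, length(target_y) >= 2)
  source_X <- as.data.frame(source_X)
  target_X <- as.data.frame(target_X)
  n_s <- nrow(source_X)
  n_t <- nrow(target_X)
  if (n_s > 0 && !identical(sort(names(source_X)), sort(names(target_X)))) {
    stop("source and target covariates differ")
  }
  if (cv_folds > n_t) {
    message("[lurtransfer] target smaller than cv_folds; reduced to ", n_t)
    cv_folds <- n_t
  }
  X_all <- if (n_s > 0) rbind(source_X, target_X[names(source_X)]) else
    target_X
  y_all <- c(source_y, target_y)
  is_target <- c(rep(FALSE, n_s), rep(TRUE, n_t))
  p0 <- n_t / (n_s + n_t)
  fracs <- p0 + (seq_len(S) - 1) / (S - 1) * (1 - p0)
  set.seed(derive_seed(seed, "tradaboost_folds"))
  folds <- sample(rep(seq_len(cv_folds), length.out = n_t))

  fit_step <- function(idx, w) {
    fit_adaboost_r2(X_all[idx, , drop = FALSE], y_all[idx],
                    weights = w[idx], n_estimators = n_estimators,
                    loss = loss, frozen_mask = !is_target[idx],
                    max_depth = max_depth)
  }

  w <- rep(1 / (n_s + n_t), n_s + n_t)  # equal initial weights
  cv_errors <- numeric(S)
  realized_frac <- numeric(S)
  models <- vector("list", S)
  history <- matrix(NA_real_, S, n_s + n_t)
  clamped <- FALSE
  for (t in seq_len(S)) {
    history[t, ] <- w
    realized_frac[t] <- sum(w[is_target])
    fold_err <- vapply(seq_len(cv_folds), function(f) {
      hold <- which(is_target)[folds == f]
      keep <- setdiff(seq_along(y_all), hold)
      m <- fit_step(keep, w)
      mean((predict(m, X_all[hold, , drop = FALSE]) - y_all[hold])^2)
    }, 0)
    cv_errors[t] <- mean(fold_err)
    models[[t]] <- fit_step(seq_along(y_all), w)
    if (t == S || n_s == 0) next
    # stage-1 update towards the next step's target-weight fraction:
    # w_source <- w_source * beta^e, beta in (0, 1] found by bisection
    resid <- abs(y_all - predict(models[[t]], X_all))[!is_target]
    D <- max(resid)
    e <- if (D < 1e-12) rep(0, n_s) else switch(loss,
      linear = resid / D,
      square = (resid / D)^2,
      exponential = 1 - exp(-resid / D))
    wt <- sum(w[is_target])
    ws <- w[!is_target]
    pow_beta <- function(beta) {
      if (beta == 0) as.numeric(e == 0) else beta^e  # 0^0 = 1 limit
    }
    frac_at <- function(beta) wt / (wt + sum(ws * pow_beta(beta)))
    want <- fracs[t + 1]
    if (frac_at(0) < want - 1e-6) {
      clamped <- TRUE  # zero-error source instances cap the fraction
      beta <- 0
    } else if (frac_at(1) >= want - 1e-6) {
      beta <- 1
    } else {
      # beta^e is extremely steep near 0: bisect on log(beta)
      lo <- log(1e-300); hi <- 0
      for (i in seq_len(200)) {
        mid <- (lo + hi) / 2
        if (frac_at(exp(mid)) < want) hi <- mid else lo <- mid
        if (abs(frac_at(exp(mid)) - want) < 1e-6) break
      }
      beta <- exp((lo + hi) / 2)
    }
    w[!is_target] <- ws * pow_beta(beta)
    w <- w / sum(w)
  }
  if (clamped) {
    message("[lurtransfer] schedule fraction unreachable; ",
            "clamped to nearest achievable value")
  }
  best_t <- which.min(cv_errors)
  structure(list(method = "tradaboost", model = models[[best_t]],
                 chosen_step = best_t - 1L, cv_errors = cv_errors,
                 schedule = fracs, realized_fractions = realized_frac,
                 weight_history = history, folds = folds,
                 n_source = n_s, n_target = n_t,
                 settings = list(S = S, n_estimators = n_estimators,
                                 cv_folds = cv_folds, loss = loss,
                                 max_depth = max_depth),
                 seed = seed),
            class = "transfer_ensemble")
}

#' Predict from a transfer-learning ensemble
#'
#' Prior_RF predicts with the reweighted forest (tree mean); TrAdaBoost
#' predicts with the weighted median of the chosen step's learners.
#' Predictions are floored at zero with the count logged.
#'
#' @param object a \code{transfer_ensemble}.
#' @param newdata covariate data frame.
#' @param ... unused.
#' @return predicted concentrations.
#' @export
predict.transfer_ensemble <- function(object, newdata, ...) {
  p <- switch(object$method,
              prior_rf = predict(object$forest, newdata),
              tradaboost = predict(object$model, newdata),
              stop("unfitted or unknown ensemble method"))
  n_floor <- sum(p < 0)
  log_count(n_floor, "transfer-model prediction(s) floored at 0")
  pmax(p, 0)
}

#' @export
print.transfer_ensemble <- function(x, ...) {
  if (x$method == "prior_rf") {
    cat("Prior_RF transfer ensemble (density-ratio-reweighted forest)\n")
    cat(sprintf("  instance weights: mean %.3f, range [%.3f, %.3f]\n",
                mean(x$instance_weights), min(x$instance_weights),
                max(x$instance_weights)))
  } else {
    cat("Two-stage TrAdaBoost.R2 transfer ensemble\n")
    cat(sprintf("  chosen step %d of %d (target-weight fraction %.3f)\n",
                x$chosen_step, length(x$schedule),
                x$schedule[x$chosen_step + 1]))
  }
  invisible(x)
}
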