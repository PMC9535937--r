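#' Run the long-term validation protocol
#'
#' Repeats the study's validation design \code{n_iterations} times.
#' Per iteration:
#' \itemize{
#'   \item the long-term sites are split 50/50 at random (by site,
#'     odd counts as ceiling(n/2) train / floor(n/2) validate);
#'   \item TrAdaBoost trains on the mobile segments plus the training
#'     half of the sites and is validated on the other half;
#'   \item SLR (fit once, outside the loop), RF_LUR and Prior_RF train
#'     on a bootstrap resample of the mobile segments and are validated
#'     on the full site set;
#'   \item the sensitivity variants RF_LUR_half and Prior_RF_half are
#'     validated on the same half used by TrAdaBoost.
#' }
#' Site-level predictions are the mean predicted concentration over
#' each site's matched segments. Metrics are nMAE, nRMSE and squared
#' Pearson R-squared; summaries are the mean, the 2.5/97.5 percentile
#' 95% CI and the median per model and metric, and improvement
#' percentages of each transfer model over each baseline are computed
#' from medians.
#'
#' @param prepared list with \code{X} (segment covariate data frame,
#'   rownames = segment ids), \code{y} (named mobile mean
#'   concentrations per segment), \code{sites} (data frame with
#'   \code{site_id}, \code{value} and list column
#'   \code{matched_segment_ids}).
#' @param models subset of \code{c("slr", "rf_lur", "prior_rf",
#'   "tradaboost", "rf_lur_half", "prior_rf_half")}.
#' @param n_iterations number of repeats (20 in the standard protocol).
#' @param seed top-level integer seed; every source of randomness
#'   derives from it.
#' @param rf_config forest configuration shared by RF_LUR and Prior_RF.
#' @param rulsif_config density-ratio configuration for Prior_RF.
#' @param slr_directions,slr_families direction spec (and optional
#'   buffer families) for the SLR baseline.
#' @param tradaboost list of TrAdaBoost settings (\code{S},
#'   \code{n_estimators}, \code{cv_folds}, \code{max_depth}).
#' @param keep_site_predictions if TRUE, keep per-iteration site-level
#'   predictions (density-plot export).
#' @return an \code{evaluation_report}: per-iteration metrics, summary
#'   table, improvement table.
#' @export
run_protocol <- function(prepared,
                         models = c("slr", "rf_lur", "prior_rf",
                                    "tradaboost"),
                         n_iterations = 20, seed = 1,
                         rf_config = lurtransfer::rf_config(),
                         rulsif_config = lurtransfer::rulsif_config(),
                         slr_directions = NULL, slr_families = NULL,
                         tradaboost = list(S = 10, n_estimators = 30,
                                           cv_folds = 5, max_depth = 6),
                         keep_site_predictions = FALSE) {
  stopifnot(n_iterations >= 2)
  X <- as.data.frame(prepared$X)
  y <- prepared$y
  sites <- prepared$sites
  stopifnot(!is.null(rownames(X)), length(y) == nrow(X),
            nrow(sites) >= 4)
  if (is.null(names(y))) names(y) <- rownames(X)
  known <- c("slr", "rf_lur", "prior_rf", "tradaboost", "rf_lur_half",
             "prior_rf_half")
  bad <- setdiff(models, known)
  if (length(bad)) {
    stop("unknown model(s): ", paste(bad, collapse = ", "),
         "; choices are ", paste(known, collapse = ", "))
  }
  n_site <- nrow(sites)
  # covariates of a site = mean covariate row over its matched segments
  site_X <- do.call(rbind, lapply(seq_len(n_site), function(i) {
    ids <- sites$matched_segment_ids[[i]]
    colMeans(X[ids, , drop = FALSE])
  }))
  site_X <- as.data.frame(site_X)

  eval_model <- function(fit_obj, site_idx) {
    seg_pred <- predict(fit_obj, X)
    names(seg_pred) <- rownames(X)
    sp <- site_predictions(seg_pred, sites[site_idx, , drop = FALSE])
    obs <- sites$value[site_idx]
    c(nmae = nmae(sp, obs), nrmse = nrmse(sp, obs),
      r2 = r2_pearson(sp, obs))
  }

  # SLR: single fit on the full mobile data (reported without a
  # bootstrap CI, as is conventional for the supervised linear model)
  slr_fit <- NULL
  if ("slr" %in% models) {
    if (is.null(slr_directions)) stop("slr requires slr_directions")
    slr_fit <- suppressMessages(
      fit_slr(X, unname(y), slr_directions, families = slr_families))
  }

  set.seed(derive_seed(seed, "protocol_iterations"))
  iter_seeds <- sample.int(2^31 - 2, n_iterations)
  rows <- list()
  failures <- list()
  site_pred_store <- if (keep_site_predictions) list() else NULL
  for (it in seq_len(n_iterations)) {
    s <- iter_seeds[it]
    set.seed(derive_seed(s, "site_split"))
    n_train <- ceiling(n_site / 2)
    train_sites <- sort(sample.int(n_site, n_train))
    val_sites <- setdiff(seq_len(n_site), train_sites)
    set.seed(derive_seed(s, "bootstrap"))
    boot <- sample.int(nrow(X), replace = TRUE)
    Xb <- X[boot, , drop = FALSE]
    rownames(Xb) <- NULL  # resampled rows; ids irrelevant for fitting
    yb <- unname(y)[boot]

    fit_one <- function(model) {
      cfg <- rf_config
      cfg$seed <- derive_seed(s, model)
      switch(model,
        slr = slr_fit,
        rf_lur = ,
        rf_lur_half = fit_rf(Xb, yb, cfg),
        prior_rf = fit_prior_rf(Xb, yb, sites$value, cfg,
                                replace_seed(rulsif_config,
                                             derive_seed(s, "rulsif"))),
        prior_rf_half = fit_prior_rf(Xb, yb, sites$value[train_sites], cfg,
                                     replace_seed(rulsif_config,
                                                  derive_seed(s, "rulsif_h"))),
        tradaboost = fit_two_stage_tradaboost_r2(
          X, unname(y), site_X[train_sites, , drop = FALSE],
          sites$value[train_sites],
          S = tradaboost$S %||% 10,
          n_estimators = tradaboost$n_estimators %||% 30,
          cv_folds = tradaboost$cv_folds %||% 5,
          max_depth = tradaboost$max_depth %||% 6,
          seed = derive_seed(s, "tradaboost")))
    }
    val_for <- function(model) {
      if (model %in% c("tradaboost", "rf_lur_half", "prior_rf_half")) {
        val_sites
      } else seq_len(n_site)
    }
    for (model in models) {
      res <- tryCatch({
        fit <- suppressMessages(fit_one(model))
        m <- eval_model(fit, val_for(model))
        if (keep_site_predictions) {
          seg_pred <- suppressMessages(predict(fit, X))
          names(seg_pred) <- rownames(X)
          sp <- site_predictions(seg_pred,
                                 sites[val_for(model), , drop = FALSE])
          site_pred_store[[length(site_pred_store) + 1]] <<- data.frame(
            iteration = it, model = model, site_id = names(sp),
            predicted = unname(sp),
            observed = sites$value[val_for(model)])
        }
        m
      }, error = function(e) e)
      if (inherits(res, "error")) {
        failures[[length(failures) + 1]] <- data.frame(
          iteration = it, model = model, message = conditionMessage(res))
      } else {
        rows[[length(rows) + 1]] <- data.frame(
          iteration = it, model = model, nmae = res[["nmae"]],
          nrmse = res[["nrmse"]], r2 = res[["r2"]])
      }
    }
  }
  per_iter <- do.call(rbind, rows)
  failures <- if (length(failures)) do.call(rbind, failures) else NULL
  if (!is.null(failures)) {
    log_count(nrow(failures), "model-iteration failure(s) excluded")
  }

  summarize <- function(v) {
    c(mean = mean(v), ci_lower = unname(stats::quantile(v, 0.025)),
      ci_upper = unname(stats::quantile(v, 0.975)),
      median = stats::median(v))
  }
  summ <- list()
  for (model in unique(per_iter$model)) {
    for (metric in c("nmae", "nrmse", "r2")) {
      v <- per_iter[per_iter$model == model, metric]
      sm <- summarize(v)
      summ[[length(summ) + 1]] <- data.frame(
        model = model, metric = metric, mean = sm[["mean"]],
        ci_lower = sm[["ci_lower"]], ci_upper = sm[["ci_upper"]],
        median = sm[["median"]], n_iterations = length(v))
    }
  }
  summary_df <- do.call(rbind, summ)

  med <- function(model, metric) {
    summary_df$median[summary_df$model == model &
                        summary_df$metric == metric]
  }
  transfer_models <- intersect(c("tradaboost", "prior_rf"), models)
  baselines <- intersect(c("slr", "rf_lur"), models)
  impr <- list()
  for (tm in transfer_models) {
    for (bm in baselines) {
      for (metric in c("nmae", "nrmse", "r2")) {
        a <- med(tm, metric); b <- med(bm, metric)
        if (!length(a) || !length(b)) next
        impr[[length(impr) + 1]] <- data.frame(
          transfer = tm, baseline = bm, metric = metric,
          improvement_pct = improvement_percentage(a, b))
      }
    }
  }
  structure(list(per_iteration = per_iter, summary = summary_df,
                 improvements = if (length(impr)) do.call(rbind, impr)
                 else NULL,
                 failures = failures,
                 site_predictions = if (keep_site_predictions)
                   do.call(rbind, site_pred_store) else NULL,
                 n_iterations = n_iterations, seed = seed,
                 models = models),
            class = "evaluation_report")
}

replace_seed <- function(config, seed) {
  config$seed <- as.integer(seed %% (2^31 - 1))
  config
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("Long-term validation report: %d iteration(s), seed %d\n",
              x$n_iterations, x$seed))
  cat("\nSummary (mean [95% CI], median):\n")
  s <- x$summary
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %-14s %-6s %.3f [%.3f, %.3f]  median %.3f\n",
                s$model[i], s$metric[i], s$mean[i], s$ci_lower[i],
                s$ci_upper[i], s$median[i]))
  }
  if (!is.null(x$improvements)) {
    cat("\nImprovement over baselines (from medians, %):\n")
    im <- x$improvements
    for (i in seq_len(nrow(im))) {
      cat(sprintf("  %-10s vs %-7s %-6s %+.1f%%\n", im$transfer[i],
                  im$baseline[i], im$metric[i], im$improvement_pct[i]))
    }
  }
  invisible(x)
}

#' Write an evaluation report to disk
#'
#' Per-iteration metrics as CSV, summary and improvements as JSON, and
#' (when present) site-level predicted-versus-observed pairs as CSV for
#' density plots.
#'
#' @param report an \code{evaluation_report}.
#' @param dir output directory (created if missing).
#' @export
write_evaluation_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_csv_prov(report$per_iteration,
                 file.path(dir, "per_iteration_metrics.csv"),
                 seed = report$seed)
  jsonlite::write_json(
    list(summary = report$summary, improvements = report$improvements,
         seed = report$seed, n_iterations = report$n_iterations),
    file.path(dir, "summary.json"), auto_unbox = TRUE, digits = NA,
    dataframe = "rows")
  if (!is.null(report$site_predictions)) {
    write_csv_prov(report$site_predictions,
                   file.path(dir, "site_predictions.csv"),
                   seed = report$seed)
  }
  invisible(dir)
}
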