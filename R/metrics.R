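#' Validation metrics: nMAE, nRMSE and squared Pearson correlation
#'
#' nMAE normalizes the mean absolute error by the mean of the
#' validation observations; nRMSE normalizes the root mean squared
#' error the same way; \code{r2_pearson} is the square of the Pearson
#' correlation between predictions and observations (affine-invariant).
#'
#' @param pred predicted concentrations.
#' @param obs observed concentrations (mean must be positive for the
#'   normalized metrics; variance positive for R-squared).
#' @return a unitless scalar.
#' @export
nmae <- function(pred, obs) {
  check_metric_inputs(pred, obs)
  if (mean(obs) <= 0) stop("mean of observations must be positive for nMAE")
  mean(abs(pred - obs)) / mean(obs)
}

#' @rdname nmae
#' @export
nrmse <- function(pred, obs) {
  check_metric_inputs(pred, obs)
  if (mean(obs) <= 0) stop("mean of observations must be positive for nRMSE")
  sqrt(mean((pred - obs)^2)) / mean(obs)
}

#' @rdname nmae
#' @export
r2_pearson <- function(pred, obs) {
  check_metric_inputs(pred, obs)
  if (stats::var(obs) == 0 || stats::var(pred) == 0) {
    stop("zero variance: squared Pearson correlation undefined")
  }
  stats::cor(pred, obs)^2
}

check_metric_inputs <- function(pred, obs) {
  if (length(pred) != length(obs)) stop("pred and obs lengths differ")
  if (length(obs) < 2) stop("need at least 2 observation pairs")
  invisible(NULL)
}

#' Improvement percentage of a transfer model over a conventional model
#'
#' \code{100 * (transfer - conventional) / conventional}, reported to
#' one decimal. Negative values mean lower error (improvement) for
#' error metrics; positive values mean improvement for R-squared.
#'
#' @param metric_transfer metric value of the transfer-learning model
#'   (median over iterations in the standard protocol).
#' @param metric_conventional metric value of the conventional model;
#'   must be positive.
#' @return percent change, rounded to one decimal.
#' @export
improvement_percentage <- function(metric_transfer, metric_conventional) {
  if (any(metric_conventional <= 0)) {
    stop("conventional metric must be positive")
  }
  round(100 * (metric_transfer - metric_conventional) / metric_conventional, 1)
}

#' Improvement table from a performance table
#'
#' Computes \code{\link{improvement_percentage}} for every combination
#' of transfer model (\code{tradaboost}, \code{prior_rf}), baseline
#' (\code{slr}, \code{rf_lur}) and metric present in a long-format
#' performance table.
#'
#' @param performance data frame with columns \code{pollutant},
#'   \code{model}, \code{metric}, \code{value}.
#' @return data frame with one improvement percentage per cell.
#' @export
improvement_table <- function(performance) {
  need <- c("pollutant", "model", "metric", "value")
  stopifnot(all(need %in% names(performance)))
  out <- list()
  for (pol in unique(performance$pollutant)) {
    pf <- performance[performance$pollutant == pol, ]
    val <- function(model, metric) {
      pf$value[pf$model == model & pf$metric == metric]
    }
    for (tm in intersect(c("tradaboost", "prior_rf"), pf$model)) {
      for (bm in intersect(c("slr", "rf_lur"), pf$model)) {
        for (metric in unique(pf$metric)) {
          a <- val(tm, metric); b <- val(bm, metric)
          if (!length(a) || !length(b)) next
          out[[length(out) + 1]] <- data.frame(
            pollutant = pol, transfer = tm, baseline = bm,
            metric = metric,
            improvement_pct = improvement_percentage(a, b))
        }
      }
    }
  }
  do.call(rbind, out)
}

#' Published long-term validation performance table
#'
#' The mean nMAE / nRMSE / squared-Pearson R-squared of the four LUR
#' models validated against external long-term near-road measurements
#' in the original mobile-monitoring campaign (NO2: 82 Palmes sites; UFP: 17
#' facade sites), shipped as plain text so the improvement arithmetic
#' can be reproduced without the undeposited raw data.
#'
#' @return long-format data frame (\code{pollutant}, \code{model},
#'   \code{metric}, \code{value}).
#' @export
published_performance <- function() {
  read_csv_prov(system.file("extdata",
                            "published_longterm_performance.csv",
                            package = "lurtransfer", mustWork = TRUE))
}

#' Aggregate segment predictions to long-term sites
#'
#' Per site, the arithmetic mean of the predicted concentrations over
#' its matched road segments (the segments within the matching radius).
#' Sites without matched segments are excluded with a warning.
#'
#' @param segment_predictions named numeric vector of predictions,
#'   names are segment ids.
#' @param sites data frame with \code{site_id} and list column
#'   \code{matched_segment_ids} (see
#'   \code{\link{match_sites_to_segments}}).
#' @return named numeric vector of per-site predictions.
#' @export
site_predictions <- function(segment_predictions, sites) {
  keep <- lengths(sites$matched_segment_ids) > 0
  if (any(!keep)) {
    warning(sum(!keep), " site(s) without matched segments excluded")
  }
  out <- vapply(which(keep), function(i) {
    ids <- sites$matched_segment_ids[[i]]
    miss <- setdiff(ids, names(segment_predictions))
    if (length(miss)) {
      stop("missing segment prediction(s): ", paste(miss, collapse = ", "))
    }
    mean(segment_predictions[ids])
  }, 0)
  names(out) <- sites$site_id[keep]
  out
}
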