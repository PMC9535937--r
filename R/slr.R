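#' Direction-constrained forward stepwise linear LUR (SLR)
#'
#' Classic supervised stepwise land-use regression. Starting from an
#' intercept-only model, the candidate covariate giving the largest
#' adjusted R-squared increase is added, but only when (a) the increase
#' exceeds \code{gain_threshold}, and (b) its coefficient sign and the
#' signs of all previously selected covariates remain as predefined
#' (e.g. positive for traffic intensity, negative for green space).
#' After forward selection, covariates with p-value above
#' \code{p_remove} are dropped and the model refit. Optionally at most
#' one member per buffer-size family may enter (standard LUR practice
#' against collinear buffer duplicates), and high-VIF covariates can be
#' pruned behind a flag.
#'
#' @param X data frame of candidate covariates (numeric, no missing
#'   values).
#' @param y concentrations, one per row of \code{X}.
#' @param directions named character vector, one of "positive" or
#'   "negative" per candidate covariate.
#' @param gain_threshold minimum adjusted R-squared gain to accept a
#'   step (default 0.01).
#' @param p_remove p-value above which a selected covariate is removed
#'   after forward selection (default 0.10).
#' @param families optional named character vector mapping covariates to
#'   a buffer family; at most one member per family is selected.
#' @param vif_prune if TRUE, iteratively drop selected covariates with
#'   variance-inflation factor above \code{max_vif}.
#' @param max_vif VIF threshold used when \code{vif_prune} is TRUE.
#' @return An object of class \code{slr_model}: intercept, coefficients,
#'   adjusted R-squared and a \code{selection_trace} log.
#' @export
fit_slr <- function(X, y, directions, gain_threshold = 0.01,
                    p_remove = 0.10, families = NULL,
                    vif_prune = FALSE, max_vif = 10) {
  X <- as.data.frame(X)
  stopifnot(nrow(X) == length(y), !anyNA(X), !anyNA(y))
  cand_all <- names(X)
  miss <- setdiff(cand_all, names(directions))
  if (length(miss)) {
    stop("no expected direction declared for: ", paste(miss, collapse = ", "))
  }
  if (!all(directions %in% c("positive", "negative"))) {
    stop("directions must be 'positive' or 'negative'")
  }
  sign_ok <- function(coefs, vars) {
    all(vapply(vars, function(v) {
      s <- if (directions[[v]] == "positive") 1 else -1
      !is.na(coefs[v]) && sign(coefs[v]) == s
    }, TRUE))
  }
  dat <- cbind(X, .y = y)
  selected <- character(0)
  cur_adj <- 0  # adjusted R^2 of the intercept-only model
  trace <- list()
  step <- 0L
  repeat {
    step <- step + 1L
    blocked_fam <- if (is.null(families)) character(0) else
      families[selected[selected %in% names(families)]]
    candidates <- setdiff(cand_all, selected)
    if (!is.null(families)) {
      candidates <- candidates[!(families[candidates] %in% blocked_fam) |
                                 is.na(families[candidates])]
    }
    if (!length(candidates)) break
    best_var <- NA_character_
    best_gain <- -Inf
    for (v in candidates) {  # column order fixes adj-R2 ties
      fml <- stats::reformulate(c(selected, v), response = ".y")
      fit <- stats::lm(fml, data = dat)
      cf <- stats::coef(fit)[-1]
      if (anyNA(cf)) {
        trace[[length(trace) + 1]] <- data.frame(
          step = step, candidate = v, adj_r2 = NA_real_, accepted = FALSE,
          reason = "rank-deficient design, skipped")
        next
      }
      adj <- summary(fit)$adj.r.squared
      gain <- adj - cur_adj
      if (!sign_ok(cf, c(selected, v))) {
        trace[[length(trace) + 1]] <- data.frame(
          step = step, candidate = v, adj_r2 = adj, accepted = FALSE,
          reason = "sign constraint violated")
        next
      }
      if (gain <= gain_threshold) {
        trace[[length(trace) + 1]] <- data.frame(
          step = step, candidate = v, adj_r2 = adj, accepted = FALSE,
          reason = sprintf("gain %.4f below threshold", gain))
        next
      }
      if (gain > best_gain) {
        best_gain <- gain
        best_var <- v
      }
    }
    if (is.na(best_var)) break
    selected <- c(selected, best_var)
    cur_adj <- cur_adj + best_gain
    trace[[length(trace) + 1]] <- data.frame(
      step = step, candidate = best_var, adj_r2 = cur_adj, accepted = TRUE,
      reason = sprintf("accepted, adj-R2 gain %.4f", best_gain))
  }
  # backward pruning on p-values
  refit <- function(vars) {
    if (!length(vars)) stats::lm(.y ~ 1, data = dat)
    else stats::lm(stats::reformulate(vars, response = ".y"), data = dat)
  }
  fit <- refit(selected)
  repeat {
    if (!length(selected)) break
    pv <- summary(fit)$coefficients[-1, 4]
    if (max(pv) <= p_remove) break
    worst <- names(which.max(pv))
    selected <- setdiff(selected, worst)
    trace[[length(trace) + 1]] <- data.frame(
      step = step, candidate = worst, adj_r2 = NA_real_, accepted = FALSE,
      reason = sprintf("removed, p=%.3f > %.2f", max(pv), p_remove))
    fit <- refit(selected)
  }
  if (isTRUE(vif_prune) && length(selected) > 1) {
    repeat {
      vifs <- vapply(selected, function(v) {
        r2 <- summary(stats::lm(
          stats::reformulate(setdiff(selected, v), response = v),
          data = dat))$r.squared
        1 / (1 - min(r2, 1 - 1e-12))
      }, 0)
      if (max(vifs) <= max_vif || length(selected) <= 1) break
      worst <- names(which.max(vifs))
      selected <- setdiff(selected, worst)
      trace[[length(trace) + 1]] <- data.frame(
        step = step, candidate = worst, adj_r2 = NA_real_, accepted = FALSE,
        reason = sprintf("removed, VIF %.1f > %.1f", max(vifs), max_vif))
      fit <- refit(selected)
    }
  }
  # enforce the sign invariant after any removal-induced refit
  repeat {
    if (!length(selected)) break
    cf <- stats::coef(fit)[-1]
    viol <- selected[vapply(selected, function(v) {
      s <- if (directions[[v]] == "positive") 1 else -1
      sign(cf[v]) != s
    }, TRUE)]
    if (!length(viol)) break
    selected <- setdiff(selected, viol[1])
    trace[[length(trace) + 1]] <- data.frame(
      step = step, candidate = viol[1], adj_r2 = NA_real_, accepted = FALSE,
      reason = "removed, sign flipped after pruning")
    fit <- refit(selected)
  }
  cf <- stats::coef(fit)
  structure(list(
    intercept = unname(cf["(Intercept)"]),
    coefficients = if (length(selected)) cf[selected] else numeric(0),
    directions = directions[selected],
    adjusted_r2 = summary(fit)$adj.r.squared,
    selection_trace = if (length(trace)) do.call(rbind, trace) else
      data.frame(step = integer(0), candidate = character(0),
                 adj_r2 = numeric(0), accepted = logical(0),
                 reason = character(0)),
    gain_threshold = gain_threshold,
    p_remove = p_remove),
    class = "slr_model")
}

#' Predict from a stepwise linear LUR model
#'
#' Linear combination of the selected covariates; predictions are
#' floored at zero (concentrations cannot be negative) and the floored
#' count is logged.
#'
#' @param object an \code{slr_model}.
#' @param newdata data frame containing all selected covariates.
#' @param ... unused.
#' @return numeric vector of predicted concentrations.
#' @export
predict.slr_model <- function(object, newdata, ...) {
  vars <- names(object$coefficients)
  miss <- setdiff(vars, names(newdata))
  if (length(miss)) {
    stop("newdata lacks selected covariate(s): ", paste(miss, collapse = ", "))
  }
  p <- rep(object$intercept, nrow(as.data.frame(newdata)))
  for (v in vars) p <- p + object$coefficients[[v]] * newdata[[v]]
  n_floor <- sum(p < 0)
  log_count(n_floor, "SLR prediction(s) floored at 0")
  pmax(p, 0)
}

#' @export
print.slr_model <- function(x, ...) {
  cat("Direction-constrained stepwise linear LUR model\n")
  cat(sprintf("  intercept: %.4g, adjusted R2: %.3f\n",
              x$intercept, x$adjusted_r2))
  if (length(x$coefficients)) {
    for (v in names(x$coefficients)) {
      cat(sprintf("  %s: %.4g (%s)\n", v, x$coefficients[[v]],
                  x$directions[[v]]))
    }
  } else cat("  (intercept-only model)\n")
  invisible(x)
}

#' Serialize / read an SLR model as human-readable key-value text
#' @param model an \code{slr_model}.
#' @param path output file.
#' @export
write_slr_model <- function(model, path) {
  lines <- c(sprintf("intercept\t%.12g", model$intercept),
             sprintf("adjusted_r2\t%.12g", model$adjusted_r2))
  for (i in seq_along(model$coefficients)) {
    v <- names(model$coefficients)[i]
    lines <- c(lines, sprintf("covariate\t%s\t%.12g\t%s\t%d", v,
                              model$coefficients[[i]],
                              model$directions[[v]], i))
  }
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_slr_model
#' @export
read_slr_model <- function(path) {
  lines <- readLines(path)
  kv <- strsplit(lines, "\t")
  intercept <- as.numeric(kv[[1]][2])
  adj <- as.numeric(kv[[2]][2])
  cov_rows <- kv[vapply(kv, function(r) r[1] == "covariate", TRUE)]
  coefs <- vapply(cov_rows, function(r) as.numeric(r[3]), 0)
  names(coefs) <- vapply(cov_rows, `[`, "", 2)
  dirs <- vapply(cov_rows, `[`, "", 4)
  names(dirs) <- names(coefs)
  structure(list(intercept = intercept, coefficients = coefs,
                 directions = dirs, adjusted_r2 = adj,
                 selection_trace = NULL),
            class = "slr_model")
}
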