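#' Random-forest configuration
#'
#' The three tuned hyperparameters of the conventional random-forest
#' LUR: number of trees, number of candidate split covariates and the
#' terminal-node cap (honoured as a depth cap with at least the
#' requested number of leaves).
#'
#' @param n_trees number of trees (default 500).
#' @param m_try candidate split covariates per node; NULL means p/3,
#'   the regression default.
#' @param max_terminal_nodes leaf cap per tree; Inf = unbounded.
#' @param seed integer seed controlling tree growth.
#' @return an \code{rf_config} object.
#' @export
rf_config <- function(n_trees = 500, m_try = NULL,
                      max_terminal_nodes = Inf, seed = 1) {
  stopifnot(n_trees >= 1, is.null(m_try) || m_try >= 1,
            max_terminal_nodes >= 1)
  structure(list(n_trees = as.integer(n_trees), m_try = m_try,
                 max_terminal_nodes = max_terminal_nodes,
                 seed = as.integer(seed)),
            class = "rf_config")
}

#' Reproducible 70/30 train/test split
#'
#' @param n number of samples (at least 10).
#' @param seed integer seed.
#' @return list with integer index vectors \code{train} and \code{test};
#'   disjoint, exhaustive, sizes within one sample of 70/30.
#' @export
split_70_30 <- function(n, seed) {
  stopifnot(n >= 10)
  set.seed(derive_seed(seed, "split_70_30"))
  n_train <- round(0.7 * n)
  train <- sort(sample.int(n, n_train))
  list(train = train, test = setdiff(seq_len(n), train))
}

#' Fit a random-forest LUR
#'
#' Bagged regression trees with \code{m_try} random split candidates,
#' optionally weighted per instance (weights act as bootstrap sampling
#' probabilities, so they are scale-free: doubling all weights leaves
#' the fit unchanged, and uniform weights reproduce the unweighted
#' fit exactly at a fixed seed).
#'
#' @param X covariate data frame.
#' @param y concentrations.
#' @param config an \code{\link{rf_config}}.
#' @param sample_weights optional nonnegative instance weights, not all
#'   zero.
#' @return an \code{rf_model}.
#' @export
fit_rf <- function(X, y, config = rf_config(), sample_weights = NULL) {
  X <- as.data.frame(X)
  stopifnot(inherits(config, "rf_config"), nrow(X) == length(y))
  p <- ncol(X)
  if (is.null(sample_weights)) sample_weights <- rep(1, nrow(X))
  if (any(sample_weights < 0)) stop("sample weights must be nonnegative")
  if (all(sample_weights == 0)) stop("all sample weights are zero")
  mtry <- min(config$m_try %||% max(1, floor(p / 3)), p)
  depth <- if (is.finite(config$max_terminal_nodes)) {
    max(1L, as.integer(ceiling(log2(config$max_terminal_nodes))))
  } else 0L  # 0 = unlimited in the tree engine
  dat <- cbind(X, .y = y)
  fit <- ranger::ranger(
    dependent.variable.name = ".y", data = dat,
    num.trees = config$n_trees, mtry = mtry, max.depth = depth,
    case.weights = sample_weights / max(sample_weights),
    seed = config$seed, num.threads = 1,
    respect.unordered.factors = "partition")
  structure(list(engine = fit, config = config, covariates = names(X),
                 y_range = range(y)),
            class = "rf_model")
}

#' @export
predict.rf_model <- function(object, newdata, ...) {
  miss <- setdiff(object$covariates, names(newdata))
  if (length(miss)) {
    stop("newdata lacks covariate(s): ", paste(miss, collapse = ", "))
  }
  p <- stats::predict(object$engine,
                      data = as.data.frame(newdata)[object$covariates],
                      num.threads = 1)$predictions
  n_floor <- sum(p < 0)
  log_count(n_floor, "RF prediction(s) floored at 0")
  pmax(p, 0)
}

#' @export
print.rf_model <- function(x, ...) {
  cat(sprintf(
    "Random-forest LUR: %d trees, m_try %s, terminal-node cap %s\n",
    x$config$n_trees, x$config$m_try %||% "default",
    format(x$config$max_terminal_nodes)))
  invisible(x)
}

# Deterministic k-fold assignment, shared across all grid points.
make_cv_folds <- function(n, k, seed) {
  set.seed(derive_seed(seed, "cv_folds"))
  sample(rep(seq_len(k), length.out = n))
}

#' Tune the random forest by k-fold cross-validation
#'
#' Evaluates every configuration of the grid on identical fold
#' assignments; the score is the mean squared-Pearson R-squared between
#' held-out predictions and observations (the study's validation
#' metric). Folds whose held-out targets have zero variance are
#' excluded with a warning.
#'
#' @param X,y training data (typically the 70% split).
#' @param grid list of \code{\link{rf_config}} objects.
#' @param k number of folds (default 5).
#' @param seed integer seed for the fold assignment.
#' @return list with \code{best_config}, \code{cv_scores} (one mean
#'   score per grid point) and the fold assignment \code{folds}.
#' @export
tune_rf <- function(X, y, grid = default_rf_grid(ncol(X)), k = 5, seed = 1) {
  stopifnot(k >= 2, length(grid) >= 1)
  X <- as.data.frame(X)
  folds <- make_cv_folds(nrow(X), k, seed)
  scores <- vapply(seq_along(grid), function(g) {
    cfg <- grid[[g]]
    fold_r2 <- vapply(seq_len(k), function(f) {
      tr <- folds != f
      if (stats::var(y[!tr]) == 0) {
        warning("fold ", f, ": zero variance in held-out targets, excluded")
        return(NA_real_)
      }
      m <- fit_rf(X[tr, , drop = FALSE], y[tr], cfg)
      r2_pearson(predict(m, X[!tr, , drop = FALSE]), y[!tr])
    }, 0)
    mean(fold_r2, na.rm = TRUE)
  }, 0)
  list(best_config = grid[[which.max(scores)]],
       cv_scores = scores, folds = folds)
}

#' Default hyperparameter grid
#' @param p number of covariates.
#' @return list of \code{rf_config} objects spanning tree count, m_try
#'   and terminal-node cap.
#' @export
default_rf_grid <- function(p) {
  mtries <- unique(pmax(1, c(floor(p / 3), floor(sqrt(p)), floor(p / 2))))
  grid <- list()
  for (nt in c(250, 500, 1000)) {
    for (mt in mtries) {
      for (mn in c(Inf, 128, 512)) {
        grid[[length(grid) + 1]] <- rf_config(nt, mt, mn)
      }
    }
  }
  grid
}

#' Overfitting check: train accuracy similar to test accuracy
#'
#' @param train_r2,test_r2 squared-Pearson accuracies in [0, 1].
#' @param tolerance maximum acceptable drop from train to test
#'   (default 0.05).
#' @return TRUE (not overfitting) iff train_r2 - test_r2 <= tolerance.
#' @export
overfit_check <- function(train_r2, test_r2, tolerance = 0.05) {
  stopifnot(train_r2 >= 0, train_r2 <= 1, test_r2 >= 0, test_r2 <= 1)
  (train_r2 - test_r2) <= tolerance
}
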