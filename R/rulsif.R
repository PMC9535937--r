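#' RuLSIF configuration
#'
#' Settings for relative unconstrained least-squares importance fitting
#' of the alpha-relative density ratio
#' \eqn{r_\alpha(x) = p_t(x) / (\alpha p_t(x) + (1-\alpha) p_s(x))}
#' between a target (long-term) and a source (mobile) sample.
#'
#' @param alpha relative parameter in [0, 1); 0 gives the plain density
#'   ratio (uLSIF), values near 1 flatten the ratio towards 1. Default
#'   0.1, a mild smoothing that keeps the estimator well-conditioned
#'   when the two distributions barely overlap in the tails.
#' @param sigma_grid Gaussian kernel bandwidths; NULL = median
#'   heuristic times \{0.5, 1, 2, 4\} (bandwidths far below the median
#'   heuristic give spiky estimates that the flat CV criterion cannot
#'   reliably reject).
#' @param lambda_grid ridge penalties (default 10^-3 .. 10, log-spaced).
#' @param n_centers maximum number of kernel centers, sampled from the
#'   target sample (default 100).
#' @param cv_folds folds for the squared-loss model selection.
#' @param seed integer seed (center subsampling and fold assignment).
#' @return a \code{rulsif_config} object.
#' @export
rulsif_config <- function(alpha = 0.1, sigma_grid = NULL,
                          lambda_grid = 10^seq(-3, 1, length.out = 5),
                          n_centers = 100, cv_folds = 5, seed = 1) {
  stopifnot(alpha >= 0, alpha < 1, length(lambda_grid) >= 1,
            n_centers >= 1, cv_folds >= 2)
  structure(list(alpha = alpha, sigma_grid = sigma_grid,
                 lambda_grid = lambda_grid, n_centers = n_centers,
                 cv_folds = cv_folds, seed = as.integer(seed)),
            class = "rulsif_config")
}

# Gaussian kernel matrix between rows of x (n x d) and centers (L x d).
gauss_kernel <- function(x, centers, sigma) {
  x <- as.matrix(x)
  centers <- as.matrix(centers)
  d2 <- outer(rowSums(x^2), rowSums(centers^2), "+") -
    2 * tcrossprod(x, centers)
  exp(-pmax(d2, 0) / (2 * sigma^2))
}

median_heuristic <- function(x, max_n = 500) {
  x <- as.matrix(x)
  if (nrow(x) > max_n) x <- x[seq(1, nrow(x), length.out = max_n), , drop = FALSE]
  d <- stats::dist(x)
  m <- stats::median(d[d > 0])
  if (!is.finite(m) || m <= 0) 1 else m
}

#' Fit a RuLSIF alpha-relative density-ratio model
#'
#' Models the ratio as a Gaussian-kernel expansion
#' \eqn{\hat r_\alpha(x) = \sum_l \theta_l K_\sigma(x, c_l)} with
#' centers \eqn{c_l} drawn from the target sample. The weights solve the
#' ridge-regularized least-squares problem
#' \eqn{\theta = (\hat H + \lambda I)^{-1} \hat h} with
#' \eqn{\hat H = \alpha\,\mathrm{mean}_t[k k^\top] +
#' (1-\alpha)\,\mathrm{mean}_s[k k^\top]} and
#' \eqn{\hat h = \mathrm{mean}_t[k]}; \eqn{(\sigma, \lambda)} are chosen
#' by k-fold cross-validation of the RuLSIF squared-loss criterion
#' \eqn{J = \alpha\,\mathrm{mean}_t[\hat r^2]/2 +
#' (1-\alpha)\,\mathrm{mean}_s[\hat r^2]/2 - \mathrm{mean}_t[\hat r]}.
#'
#' @param target_samples numeric vector (or matrix) from the target
#'   (long-term) distribution.
#' @param source_samples numeric vector (or matrix) from the source
#'   (mobile) distribution.
#' @param config a \code{\link{rulsif_config}}.
#' @return a \code{rulsif_model} with centers, theta and the selected
#'   sigma and lambda.
#' @export
fit_rulsif <- function(target_samples, source_samples,
                       config = rulsif_config()) {
  xt <- as.matrix(target_samples)
  xs <- as.matrix(source_samples)
  stopifnot(nrow(xt) >= 1, nrow(xs) >= 1, ncol(xt) == ncol(xs))
  if (stats::var(as.numeric(xt)) == 0 && stats::var(as.numeric(xs)) == 0) {
    stop("both samples are constant: density ratio undefined")
  }
  set.seed(derive_seed(config$seed, "rulsif_centers"))
  L <- min(config$n_centers, nrow(xt))
  centers <- xt[sample.int(nrow(xt), L), , drop = FALSE]
  sigmas <- config$sigma_grid %||%
    (median_heuristic(rbind(xt, xs)) * c(0.5, 1, 2, 4))
  lambdas <- sort(config$lambda_grid)
  alpha <- config$alpha
  k <- min(config$cv_folds, nrow(xt), nrow(xs))
  set.seed(derive_seed(config$seed, "rulsif_folds"))
  ft <- sample(rep(seq_len(k), length.out = nrow(xt)))
  fs <- sample(rep(seq_len(k), length.out = nrow(xs)))

  solve_theta <- function(Kt, Ks, lambda) {
    H <- alpha * crossprod(Kt) / nrow(Kt) +
      (1 - alpha) * crossprod(Ks) / nrow(Ks)
    h <- colMeans(Kt)
    solve(H + lambda * diag(ncol(Kt)), h)
  }
  jloss <- function(rt, rs) {
    alpha * mean(rt^2) / 2 + (1 - alpha) * mean(rs^2) / 2 - mean(rt)
  }

  best <- list(score = Inf, sigma = sigmas[1], lambda = lambdas[1])
  for (sg in sigmas) {
    Kt <- gauss_kernel(xt, centers, sg)
    Ks <- gauss_kernel(xs, centers, sg)
    for (lm in lambdas) {
      cv <- vapply(seq_len(k), function(f) {
        th <- tryCatch(
          solve_theta(Kt[ft != f, , drop = FALSE],
                      Ks[fs != f, , drop = FALSE], lm),
          error = function(e) NULL)
        if (is.null(th)) return(NA_real_)
        jloss(Kt[ft == f, , drop = FALSE] %*% th,
              Ks[fs == f, , drop = FALSE] %*% th)
      }, 0)
      sc <- mean(cv)
      if (is.finite(sc) && sc < best$score) {
        best <- list(score = sc, sigma = sg, lambda = lm)
      }
    }
  }
  # final fit; a singular system escalates lambda along the grid
  Kt <- gauss_kernel(xt, centers, best$sigma)
  Ks <- gauss_kernel(xs, centers, best$sigma)
  theta <- NULL
  for (lm in lambdas[lambdas >= best$lambda]) {
    theta <- tryCatch(solve_theta(Kt, Ks, lm), error = function(e) NULL)
    if (!is.null(theta)) {
      if (lm > best$lambda) {
        message("[lurtransfer] singular system; lambda increased to ", lm)
      }
      best$lambda <- lm
      break
    }
  }
  if (is.null(theta)) stop("RuLSIF system singular for every lambda in grid")
  structure(list(centers = centers, theta = as.numeric(theta),
                 sigma = best$sigma, lambda = best$lambda, alpha = alpha,
                 cv_score = best$score),
            class = "rulsif_model")
}

#' @export
predict.rulsif_model <- function(object, newdata, ...) {
  K <- gauss_kernel(as.matrix(newdata), object$centers, object$sigma)
  as.numeric(K %*% object$theta)
}

#' Evaluate the fitted density ratio as instance weights
#'
#' Returns \code{max(r_hat(point), floor)}; the positive floor keeps
#' every training instance minimally represented (no zero-weight
#' degenerate trees).
#'
#' @param model a fitted \code{rulsif_model}.
#' @param points concentrations (typically the source instances'
#'   responses).
#' @param floor minimum weight (default 1e-3).
#' @return nonnegative weights, one per point.
#' @export
evaluate_ratio <- function(model, points, floor = 1e-3) {
  stopifnot(inherits(model, "rulsif_model"), floor > 0)
  pmax(predict(model, points), floor)
}

#' @export
print.rulsif_model <- function(x, ...) {
  cat(sprintf(
    "RuLSIF ratio model: alpha %.2f, sigma %.3g, lambda %.3g, %d centers\n",
    x$alpha, x$sigma, x$lambda, nrow(x$centers)))
  invisible(x)
}

#' Serialize / read a RuLSIF model as JSON
#' @param model a \code{rulsif_model}.
#' @param path output file.
#' @export
write_rulsif_model <- function(model, path) {
  jsonlite::write_json(
    list(centers = unclass(model$centers), theta = model$theta,
         sigma = model$sigma, lambda = model$lambda, alpha = model$alpha),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_rulsif_model
#' @export
read_rulsif_model <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(centers = as.matrix(j$centers), theta = as.numeric(j$theta),
                 sigma = j$sigma, lambda = j$lambda, alpha = j$alpha),
            class = "rulsif_model")
}
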