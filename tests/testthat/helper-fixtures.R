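# Shared fixtures and independent oracles, built in code at test time.

# --- geometry oracles -------------------------------------------------

# brute-force point-to-segment distance (scalar, loop form)
oracle_point_edge_dist <- function(p, a, b) {
  ab <- b - a
  len2 <- sum(ab^2)
  if (len2 == 0) return(sqrt(sum((p - a)^2)))
  t <- max(0, min(1, sum((p - a) * ab) / len2))
  proj <- a + t * ab
  sqrt(sum((p - proj)^2))
}

oracle_point_polyline_dist <- function(p, v) {
  min(vapply(seq_len(nrow(v) - 1), function(i) {
    oracle_point_edge_dist(p, v[i, ], v[i + 1, ])
  }, 0))
}

# exhaustive nearest-segment assignment with the lexicographic tie rule
oracle_snap <- function(pts, segments, max_dist) {
  vapply(seq_len(nrow(pts)), function(i) {
    d <- vapply(seq_len(nrow(segments)), function(j) {
      oracle_point_polyline_dist(pts[i, ], segments$vertices[[j]])
    }, 0)
    dmin <- min(d)
    if (dmin > max_dist) return(NA_character_)
    min(segments$segment_id[d == dmin])
  }, "")
}

# --- simulation fixtures ----------------------------------------------

# a small prepared scene: campaign -> corrected/snapped/aggregated data
# plus matched long-term sites; the workhorse for model-level tests
make_prepared_scene <- function(seed, shift, n_streets = 6) {
  scene <- generate_scene(scene_config(n_streets = n_streets, seed = seed))
  camp <- generate_mobile_campaign(scene, shift, seed = seed + 1000)
  mode <- if (shift$pollutant == "UFP") "multiplicative" else "additive"
  obs <- suppressMessages(
    temporal_correct(camp$observations, camp$reference, mode))
  obs <- suppressMessages(snap_to_segments(obs, scene$segments))
  obs <- obs[!is.na(obs$segment_id), , drop = FALSE]
  agg <- aggregate_segments(obs)
  sites <- generate_longterm_network(scene, shift, seed = seed + 2000)
  sites <- suppressMessages(match_sites_to_segments(sites, scene$segments))
  y <- agg$mean_conc
  names(y) <- agg$segment_id
  X <- scene$X[agg$segment_id, , drop = FALSE]
  n_site <- nrow(sites)
  site_X <- as.data.frame(do.call(rbind, lapply(seq_len(n_site), function(i) {
    colMeans(scene$X[sites$matched_segment_ids[[i]], , drop = FALSE])
  })))
  list(scene = scene, X = X, y = y, sites = sites, site_X = site_X)
}

# long-term nMAE of a fitted model over (a subset of) the sites
site_nmae <- function(fit, prep, site_idx = seq_len(nrow(prep$sites))) {
  p <- suppressMessages(predict(fit, prep$scene$X))
  names(p) <- rownames(prep$scene$X)
  sp <- site_predictions(p, prep$sites[site_idx, , drop = FALSE])
  nmae(sp, prep$sites$value[site_idx])
}

# one full comparison under a given shift: RF_LUR (full validation),
# Prior_RF (full validation), TrAdaBoost (trained on half the sites,
# validated on the other half) -- the published comparison design
compare_models_once <- function(seed, shift, n_trees = 250) {
  prep <- make_prepared_scene(seed, shift)
  cfg <- rf_config(n_trees = n_trees, seed = seed)
  rf <- fit_rf(prep$X, unname(prep$y), cfg)
  pr <- suppressMessages(
    fit_prior_rf(prep$X, unname(prep$y), prep$sites$value, cfg,
                 rulsif_config(seed = seed)))
  n_site <- nrow(prep$sites)
  set.seed(seed)
  tr <- sort(sample.int(n_site, ceiling(n_site / 2)))
  va <- setdiff(seq_len(n_site), tr)
  tb <- suppressMessages(fit_two_stage_tradaboost_r2(
    prep$X, unname(prep$y), prep$site_X[tr, , drop = FALSE],
    prep$sites$value[tr], S = 10, n_estimators = 30, seed = seed))
  c(rf = site_nmae(rf, prep),
    prior_rf = site_nmae(pr, prep),
    tradaboost = site_nmae(tb, prep, va))
}

# --- independent reimplementation of AdaBoost.R2 ----------------------
# step-by-step reference with explicit loops, kept deliberately naive;
# shares only the base-learner call with the implementation under test
oracle_adaboost_weights <- function(X, y, n_iter, max_depth = 2,
                                    frozen = rep(FALSE, length(y))) {
  n <- length(y)
  w <- rep(1 / n, n)
  history <- list()
  for (m in seq_len(n_iter)) {
    dat <- cbind(as.data.frame(X), .y = y)
    tree <- rpart::rpart(.y ~ ., data = dat, weights = w * n,
                         method = "anova",
                         control = rpart::rpart.control(
                           maxdepth = max_depth, cp = 0, minsplit = 5,
                           minbucket = 2, xval = 0))
    pred <- predict(tree, dat)
    r <- abs(y - pred)
    D <- max(r)
    if (D < 1e-12) break
    e <- r / D
    eps <- sum(w * e)
    if (eps >= 0.5) break
    beta <- eps / (1 - eps)
    for (i in seq_len(n)) {
      if (!frozen[i]) w[i] <- w[i] * beta^(1 - e[i])
    }
    w <- w / sum(w)
    history[[m]] <- w
  }
  history
}

# brute-force weighted median: scan sorted cumulative weights
oracle_weighted_median <- function(values, weights) {
  ord <- order(values)
  cw <- cumsum(weights[ord])
  values[ord][which(cw >= sum(weights) / 2)[1]]
}

# --- naive uLSIF (alpha = 0) ------------------------------------------
# direct double-loop implementation of the ratio estimator for a fixed
# sigma, lambda and center set
oracle_ulsif <- function(target, source, centers, sigma, lambda, points) {
  L <- length(centers)
  K <- function(x, c) exp(-(x - c)^2 / (2 * sigma^2))
  H <- matrix(0, L, L)
  for (i in seq_along(source)) {
    k <- vapply(centers, function(c) K(source[i], c), 0)
    H <- H + outer(k, k)
  }
  H <- H / length(source)
  h <- rep(0, L)
  for (i in seq_along(target)) {
    h <- h + vapply(centers, function(c) K(target[i], c), 0)
  }
  h <- h / length(target)
  theta <- solve(H + lambda * diag(L), h)
  vapply(points, function(p) {
    sum(theta * vapply(centers, function(c) K(p, c), 0))
  }, 0)
}
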