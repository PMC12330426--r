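## Ridge baseline: closed-form L2-penalized linear regression on
## standardized features, with grouped K-fold validation metrics.

ridge_solve <- function(X, y, lambda) {
  p <- ncol(X)
  A <- crossprod(X) + diag(lambda, p)
  drop(solve(A, crossprod(X, y)))
}

## standardize with training-set statistics; zero-variance columns get unit
## scale so they contribute nothing after centering
ridge_stats <- function(X) {
  mu <- colMeans(X)
  sds <- apply(X, 2L, stats::sd)
  sds[sds == 0] <- 1
  list(mu = mu, sd = sds)
}

ridge_apply_stats <- function(X, st) {
  sweep(sweep(X, 2L, st$mu, "-"), 2L, st$sd, "/")
}

fit_cv_ridge <- function(X, y, spec, cfg, fold_id) {
  k <- cfg$folds
  fold_mae <- fold_r <- numeric(k)
  oof <- rep(NA_real_, length(y))
  for (f in seq_len(k)) {
    tr <- fold_id != f; va <- !tr
    st <- ridge_stats(X[tr, , drop = FALSE])
    Xtr <- ridge_apply_stats(X[tr, , drop = FALSE], st)
    mu_y <- mean(y[tr]); sd_y <- stats::sd(y[tr]); if (sd_y == 0) sd_y <- 1
    beta <- ridge_solve(Xtr, (y[tr] - mu_y) / sd_y, spec$ridge_penalty)
    pred <- drop(ridge_apply_stats(X[va, , drop = FALSE], st) %*% beta) *
      sd_y + mu_y
    oof[va] <- pred
    ev <- evaluate_predictions(pred, y[va])
    fold_mae[f] <- ev$mae; fold_r[f] <- ev$r
  }
  st <- ridge_stats(X)
  mu_y <- mean(y); sd_y <- stats::sd(y); if (sd_y == 0) sd_y <- 1
  beta <- ridge_solve(ridge_apply_stats(X, st), (y - mu_y) / sd_y,
                      spec$ridge_penalty)
  list(params = list(beta = beta),
       y_center = mu_y, y_scale = sd_y, feature_stats = st,
       summary = list(fold_mae = fold_mae, fold_r = fold_r,
                      best_epoch = rep(NA_integer_, k),
                      selected_epoch = NA_integer_,
                      fold_id = fold_id, oof_predictions = oof))
}

## predictions on the standardized-target scale (unscaled by predict_age)
ridge_predict <- function(model, X) {
  drop(ridge_apply_stats(X, model$feature_stats) %*% model$params$beta)
}
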