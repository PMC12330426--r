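## Shared machinery for the gradient-trained families (graph_conv, bilstm):
## Adam optimizer, MAE loss, minibatch loop, per-fold validation curves,
## best-epoch selection and final refit. Everything runs on the
## standardized-age scale; predict_age restores years.

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

glorot <- function(n_in, n_out) {
  lim <- sqrt(6 / (n_in + n_out))
  matrix(stats::runif(n_in * n_out, -lim, lim), n_in, n_out)
}

## family interface: list(init(spec, shape), loss_grad(params, inputs, y,
## spec, train), predict(params, inputs))
neural_family <- function(family) {
  switch(family,
    graph_conv = list(init = gcn_init, loss_grad = gcn_loss_grad,
                      predict = gcn_predict),
    bilstm = list(init = lstm_init, loss_grad = lstm_loss_grad,
                  predict = lstm_predict),
    stop("unknown neural family: ", family))
}

## one training run of `epochs` epochs on inputs[idx]; returns params and,
## when val_idx is given, the per-epoch validation predictions
neural_train_run <- function(fam, spec, cfg, inputs, ys, idx, epochs,
                             val_idx = NULL) {
  params <- fam$init(spec, dim_of_inputs(inputs))
  state <- adam_init(params)
  val_pred <- if (!is.null(val_idx))
    matrix(NA_real_, length(val_idx), epochs) else NULL
  for (ep in seq_len(epochs)) {
    order_idx <- idx[sample.int(length(idx))]
    starts <- seq(1L, length(order_idx), by = cfg$batch_size)
    for (s in starts) {
      b <- order_idx[s:min(s + cfg$batch_size - 1L, length(order_idx))]
      lg <- fam$loss_grad(params, subset_inputs(inputs, b), ys[b], spec)
      if (!is.finite(lg$loss))
        stop("non-finite training loss (divergence) at epoch ", ep)
      st <- adam_step(params, lg$grads, state, cfg$learning_rate)
      params <- st$params; state <- st$state
    }
    if (!is.null(val_idx))
      val_pred[, ep] <- fam$predict(params, subset_inputs(inputs, val_idx))
  }
  list(params = params, val_pred = val_pred)
}

dim_of_inputs <- function(inputs) {
  if (is.matrix(inputs)) dim(inputs) else dim(inputs[[1]])
}

subset_inputs <- function(inputs, idx) {
  if (is.matrix(inputs)) inputs[idx, , drop = FALSE] else inputs[idx]
}

fit_cv_neural <- function(inputs, y, spec, cfg, fold_id) {
  fam <- neural_family(spec$family)
  mu_y <- mean(y); sd_y <- stats::sd(y); if (sd_y == 0) sd_y <- 1
  ys <- (y - mu_y) / sd_y
  k <- cfg$folds
  fold_mae <- fold_r <- numeric(k)
  best_epoch <- integer(k)
  oof <- rep(NA_real_, length(y))
  for (f in seq_len(k)) {
    tr <- which(fold_id != f); va <- which(fold_id == f)
    run <- neural_train_run(fam, spec, cfg, inputs, ys, tr, cfg$epochs,
                            val_idx = va)
    pred_years <- run$val_pred * sd_y + mu_y
    mae_curve <- colMeans(abs(pred_years - y[va]))
    best_epoch[f] <- which.min(mae_curve)
    best <- pred_years[, best_epoch[f]]
    oof[va] <- best
    ev <- evaluate_predictions(best, y[va])
    fold_mae[f] <- ev$mae; fold_r[f] <- ev$r
  }
  selected <- as.integer(round(stats::median(best_epoch)))
  refit <- neural_train_run(fam, spec, cfg, inputs, ys, seq_along(y),
                            selected)
  list(params = refit$params, y_center = mu_y, y_scale = sd_y,
       feature_stats = NULL,
       summary = list(fold_mae = fold_mae, fold_r = fold_r,
                      best_epoch = best_epoch, selected_epoch = selected,
                      fold_id = fold_id, oof_predictions = oof))
}
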