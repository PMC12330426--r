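## Bidirectional stacked LSTM regressor on dynamic-FNC window sequences.
##
## Each direction runs its own stack of LSTM layers over the sequence (the
## backward direction over the time-reversed sequence); the final hidden
## states of the top layer of both directions are concatenated and read out
## linearly. Gates use the standard formulation
##   i,f,o = sigmoid, g = tanh, c_t = f*c_{t-1} + i*g, h_t = o*tanh(c_t).
## Dropout (inverted) is applied between stacked layers during training
## only. Training is Adam on MAE at the standardized-age scale; forward and
## backward passes are batched (matrices of batch x units per timestep).

sigmoid <- function(x) 1 / (1 + exp(-x))

lstm_layer_names <- function(dir, layer) {
  base <- paste0(dir, layer)
  c(Wx = paste0("Wx_", base), Wh = paste0("Wh_", base), b = paste0("b_", base))
}

lstm_init <- function(spec, shape) {
  p <- shape[2]
  H <- spec$hidden_units
  L <- spec$recurrent_layers
  params <- list()
  for (dir in c("f", "b")) {
    for (l in seq_len(L)) {
      nin <- if (l == 1L) p else H
      nms <- lstm_layer_names(dir, l)
      params[[nms["Wx"]]] <- glorot(nin, 4L * H)
      params[[nms["Wh"]]] <- glorot(H, 4L * H)
      b <- rep(0, 4L * H)
      b[(H + 1L):(2L * H)] <- 1        # forget-gate bias init
      params[[nms["b"]]] <- b
    }
  }
  params$w_out <- glorot(2L * H, 1L)
  params$b_out <- matrix(0, 1, 1)
  attr(params, "spec") <- spec      # predict() needs the architecture
  params
}

## forward pass of one directional stack over a batch.
## xs: list over time of B x p matrices. Returns caches and top-layer
## final hidden state.
lstm_stack_forward <- function(params, xs, dir, spec, drop_masks = NULL) {
  H <- spec$hidden_units
  L <- spec$recurrent_layers
  Tn <- length(xs)
  B <- nrow(xs[[1]])
  layers <- vector("list", L)
  input <- xs
  for (l in seq_len(L)) {
    nms <- lstm_layer_names(dir, l)
    Wx <- params[[nms["Wx"]]]; Wh <- params[[nms["Wh"]]]
    b <- params[[nms["b"]]]
    h <- matrix(0, B, H); c <- matrix(0, B, H)
    cache <- vector("list", Tn)
    out <- vector("list", Tn)
    for (t in seq_len(Tn)) {
      G <- sweep(input[[t]] %*% Wx + h %*% Wh, 2L, b, "+")
      ii <- sigmoid(G[, 1:H, drop = FALSE])
      ff <- sigmoid(G[, (H + 1):(2 * H), drop = FALSE])
      oo <- sigmoid(G[, (2 * H + 1):(3 * H), drop = FALSE])
      gg <- tanh(G[, (3 * H + 1):(4 * H), drop = FALSE])
      c_new <- ff * c + ii * gg
      tc <- tanh(c_new)
      h_new <- oo * tc
      cache[[t]] <- list(x = input[[t]], h_prev = h, c_prev = c,
                         i = ii, f = ff, o = oo, g = gg, tc = tc)
      h <- h_new; c <- c_new
      out[[t]] <- h
    }
    layers[[l]] <- list(cache = cache, out = out, final_h = h)
    if (l < L) {
      if (!is.null(drop_masks)) {
        mask <- drop_masks[[dir]][[l]]
        out <- lapply(out, function(m) m * mask)
        layers[[l]]$mask <- mask
      }
      input <- out
    }
  }
  layers
}

## backward pass through one directional stack.
## d_final: B x H gradient on the top layer's final hidden state.
lstm_stack_backward <- function(params, layers, dir, spec, d_final, grads) {
  H <- spec$hidden_units
  L <- spec$recurrent_layers
  Tn <- length(layers[[1]]$cache)
  B <- nrow(d_final)
  d_out <- NULL                      # per-timestep grads from layer above
  for (l in rev(seq_len(L))) {
    nms <- lstm_layer_names(dir, l)
    Wx <- params[[nms["Wx"]]]; Wh <- params[[nms["Wh"]]]
    cache <- layers[[l]]$cache
    dWx <- Wx * 0; dWh <- Wh * 0; db <- numeric(4L * H)
    dh <- matrix(0, B, H); dc <- matrix(0, B, H)
    if (l == L) dh <- dh + d_final
    d_below <- vector("list", Tn)
    for (t in rev(seq_len(Tn))) {
      if (!is.null(d_out)) dh <- dh + d_out[[t]]
      cc <- cache[[t]]
      do_ <- dh * cc$tc
      dc <- dc + dh * cc$o * (1 - cc$tc^2)
      di <- dc * cc$g
      dg <- dc * cc$i
      df <- dc * cc$c_prev
      dc <- dc * cc$f                     # becomes dc_prev
      dG <- cbind(di * cc$i * (1 - cc$i),
                  df * cc$f * (1 - cc$f),
                  do_ * cc$o * (1 - cc$o),
                  dg * (1 - cc$g^2))
      dWx <- dWx + crossprod(cc$x, dG)
      dWh <- dWh + crossprod(cc$h_prev, dG)
      db <- db + colSums(dG)
      d_below[[t]] <- dG %*% t(Wx)
      dh <- dG %*% t(Wh)                  # becomes dh_prev
    }
    grads[[nms["Wx"]]] <- grads[[nms["Wx"]]] + dWx
    grads[[nms["Wh"]]] <- grads[[nms["Wh"]]] + dWh
    grads[[nms["b"]]] <- grads[[nms["b"]]] + db
    if (l > 1L) {
      if (!is.null(layers[[l - 1L]]$mask)) {
        mask <- layers[[l - 1L]]$mask
        d_below <- lapply(d_below, function(m) m * mask)
      }
      d_out <- d_below
    }
  }
  grads
}

## assemble batch time-slices for both directions
lstm_batch_slices <- function(inputs) {
  Tn <- nrow(inputs[[1]])
  xs <- lapply(seq_len(Tn), function(t)
    do.call(rbind, lapply(inputs, function(s) s[t, ])))
  list(fwd = xs, bwd = rev(xs))
}

lstm_forward_batch <- function(params, inputs, spec, training = FALSE) {
  slices <- lstm_batch_slices(inputs)
  B <- length(inputs)
  H <- spec$hidden_units
  drop_masks <- NULL
  if (training && spec$dropout > 0 && spec$recurrent_layers > 1L) {
    keep <- 1 - spec$dropout
    drop_masks <- list()
    for (dir in c("f", "b")) {
      drop_masks[[dir]] <- lapply(seq_len(spec$recurrent_layers - 1L),
        function(l) matrix(stats::rbinom(B * H, 1L, keep) / keep, B, H))
    }
  }
  fwd <- lstm_stack_forward(params, slices$fwd, "f", spec, drop_masks)
  bwd <- lstm_stack_forward(params, slices$bwd, "b", spec, drop_masks)
  hcat <- cbind(fwd[[spec$recurrent_layers]]$final_h,
                bwd[[spec$recurrent_layers]]$final_h)
  yhat <- drop(hcat %*% params$w_out) + params$b_out[1, 1]
  list(yhat = yhat, fwd = fwd, bwd = bwd, hcat = hcat)
}

lstm_predict <- function(params, inputs) {
  lstm_forward_batch(params, inputs, attr(params, "spec"))$yhat
}

lstm_loss_grad <- function(params, inputs, y, spec) {
  fw <- lstm_forward_batch(params, inputs, spec, training = TRUE)
  n <- length(y)
  res <- fw$yhat - y
  loss <- mean(abs(res))
  dy <- sign(res) / n
  grads <- lapply(params, function(p) p * 0)
  grads$w_out <- crossprod(fw$hcat, dy)
  grads$b_out <- matrix(sum(dy), 1, 1)
  dhcat <- dy %*% t(params$w_out)        # n x 2H
  H <- spec$hidden_units
  grads <- lstm_stack_backward(params, fw$fwd, "f", spec,
                               dhcat[, 1:H, drop = FALSE], grads)
  grads <- lstm_stack_backward(params, fw$bwd, "b", spec,
                               dhcat[, (H + 1):(2 * H), drop = FALSE], grads)
  list(loss = loss, grads = grads)
}
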