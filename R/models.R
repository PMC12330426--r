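#' Model specification for brain-age regressors
#'
#' Describes one of the three supported regression families:
#' * `ridge` — linear ridge regression on connectivity feature vectors; a
#'   fast, fully deterministic baseline.
#' * `graph_conv` — a graph-convolutional network on the static FNC matrix:
#'   the row-normalized absolute FNC serves as the propagation operator and
#'   the FNC rows as node features; ReLU hidden layers, global mean pooling,
#'   linear readout.
#' * `bilstm` — a bidirectional stacked LSTM over the dynamic-FNC window
#'   sequence; the last hidden states of both directions are concatenated
#'   and read out linearly.
#'
#' @param family One of `"ridge"`, `"graph_conv"`, `"bilstm"`.
#' @param hidden_units LSTM hidden units per layer and direction.
#' @param recurrent_layers Number of stacked LSTM layers.
#' @param dropout Dropout rate between recurrent layers during training
#'   (disabled at inference).
#' @param graph_layer_sizes Output sizes of the graph-convolution layers.
#' @param ridge_penalty Non-negative L2 penalty for the ridge family.
#' @return A `model_spec` list.
#' @export
model_spec <- function(family = c("ridge", "graph_conv", "bilstm"),
                       hidden_units = 128,
                       recurrent_layers = 3,
                       dropout = 0.1,
                       graph_layer_sizes = c(64, 32),
                       ridge_penalty = 1) {
  family <- match.arg(family)
  stopifnot(dropout >= 0, dropout < 1, hidden_units >= 1,
            recurrent_layers >= 1, length(graph_layer_sizes) >= 1,
            all(graph_layer_sizes >= 1), ridge_penalty >= 0)
  structure(list(family = family,
                 hidden_units = as.integer(hidden_units),
                 recurrent_layers = as.integer(recurrent_layers),
                 dropout = dropout,
                 graph_layer_sizes = as.integer(graph_layer_sizes),
                 ridge_penalty = ridge_penalty),
            class = "model_spec")
}

#' Training configuration
#'
#' Cross-validated training protocol: Adam optimization of mean absolute
#' error in minibatches, K-fold cross-validation with subjects never
#' spanning folds, per-fold validation curves, and final refit on all data
#' at the epoch count selected by the minimum mean validation MAE rule
#' (median of per-fold best epochs).
#'
#' @param learning_rate Adam learning rate.
#' @param batch_size Minibatch size.
#' @param epochs Training epochs per fold.
#' @param folds Number of cross-validation folds K (>= 2).
#' @param seed Integer seed controlling fold assignment, initialization,
#'   batching and dropout.
#' @return A `training_config` list.
#' @export
training_config <- function(learning_rate = 1e-3, batch_size = 64,
                            epochs = 100, folds = 5, seed = 1L) {
  stopifnot(learning_rate > 0, batch_size >= 1, epochs >= 1, folds >= 2)
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 folds = as.integer(folds),
                 seed = as.integer(seed)),
            class = "training_config")
}

## internal: fold assignment grouped by subject id, so multiple scans of one
## subject never span folds. Returns integer fold label per row.
make_grouped_folds <- function(subject_ids, k) {
  subs <- unique(subject_ids)
  if (length(subs) < k)
    stop("fewer subjects (", length(subs), ") than folds (", k, ")")
  perm <- sample(subs)
  fold_of_sub <- rep(seq_len(k), length.out = length(subs))
  names(fold_of_sub) <- perm
  unname(fold_of_sub[as.character(subject_ids)])
}

#' Evaluate age predictions
#'
#' Pearson correlation and mean absolute error between predicted and
#' chronological age.
#'
#' @param predicted,chronological Numeric vectors of equal length (>= 3).
#' @return List with `r` and `mae` (years). When the predictions are
#'   constant, `r` is `NA` with a warning (the MAE is still returned).
#' @export
evaluate_predictions <- function(predicted, chronological) {
  if (length(predicted) != length(chronological))
    stop("predicted and chronological must have equal length")
  if (length(predicted) < 3L) stop("need at least 3 pairs")
  mae <- mean(abs(predicted - chronological))
  if (stats::sd(predicted) == 0 || stats::sd(chronological) == 0) {
    warning("correlation undefined for constant predictions")
    return(list(r = NA_real_, mae = mae))
  }
  list(r = stats::cor(predicted, chronological), mae = mae)
}

## internal: input container checks per family
check_model_inputs <- function(features, family) {
  if (family == "ridge") {
    X <- as.matrix(features)
    if (!is.numeric(X)) stop("ridge features must be a numeric matrix")
    return(list(n = nrow(X), inputs = X, shape = c(ncol(X))))
  }
  if (!is.list(features))
    stop(family, " features must be a list (one element per subject)")
  if (family == "graph_conv") {
    mats <- lapply(features, fnc_matrix)
    dims <- vapply(mats, function(m) dim(m), integer(2))
    if (any(dims != dims[1, 1]))
      stop("all FNC matrices must be square with identical size")
    return(list(n = length(mats), inputs = mats, shape = dim(mats[[1]])))
  }
  # bilstm: list of T x p window-feature matrices
  seqs <- lapply(features, as.matrix)
  dims <- vapply(seqs, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("all dFNC sequences must share the same T x p shape; got ",
         paste(unique(apply(dims, 2, paste, collapse = "x")), collapse = ", "))
  list(n = length(seqs), inputs = seqs, shape = dim(seqs[[1]]))
}

#' Train a brain-age predictor with K-fold cross-validation
#'
#' Runs grouped K-fold cross-validation (one subject never spans folds),
#' records per-fold validation curves, selects the epoch with optimal
#' cross-validation MAE (median of per-fold best epochs) and refits the
#' model on all data for that many epochs. The ridge family has no epochs:
#' its fold models are closed-form fits and the final model is the
#' closed-form fit on all data. Ages are internally standardized for
#' gradient training and predictions are returned in years. Deterministic
#' given `train_cfg$seed`.
#'
#' @param features Per-subject features: a numeric matrix (rows = subjects)
#'   for `ridge`; a list of C x C FNC matrices for `graph_conv`; a list of
#'   T x p window-feature matrices for `bilstm`.
#' @param ages Chronological ages in years.
#' @param spec A [model_spec()].
#' @param train_cfg A [training_config()].
#' @param subject_ids Optional subject identifier per row (defaults to one
#'   subject per row); used to group folds.
#' @param scope Feature scope label stored on the model (`"wide"` or a
#'   network name).
#' @param modality Input modality label (`"sfnc"` or `"dfnc"`).
#' @return A `trained_predictor` with fitted parameters, the spec, and a
#'   `training` summary (per-fold validation MAE and r, per-fold best
#'   epoch, selected epoch, out-of-fold predictions).
#' @export
train_predictor <- function(features, ages, spec, train_cfg = training_config(),
                            subject_ids = NULL, scope = "wide",
                            modality = c("sfnc", "dfnc")) {
  stopifnot(inherits(spec, "model_spec"), inherits(train_cfg, "training_config"))
  modality <- match.arg(modality)
  chk <- check_model_inputs(features, spec$family)
  n <- chk$n
  ages <- as.numeric(ages)
  if (length(ages) != n) stop("ages length must match number of subjects")
  if (any(!is.finite(ages))) stop("ages must be finite")
  if (is.null(subject_ids)) subject_ids <- as.character(seq_len(n))
  if (n < 2L * train_cfg$folds)
    stop("need at least 2 subjects per fold: n = ", n,
         ", folds = ", train_cfg$folds)
  set.seed(train_cfg$seed)
  fold_id <- make_grouped_folds(subject_ids, train_cfg$folds)

  fit <- if (spec$family == "ridge") {
    fit_cv_ridge(chk$inputs, ages, spec, train_cfg, fold_id)
  } else {
    fit_cv_neural(chk$inputs, ages, spec, train_cfg, fold_id)
  }
  structure(list(spec = spec, family = spec$family, scope = scope,
                 modality = modality, input_shape = chk$shape,
                 params = fit$params, y_center = fit$y_center,
                 y_scale = fit$y_scale, feature_stats = fit$feature_stats,
                 training = fit$summary),
            class = "trained_predictor")
}

#' @export
print.trained_predictor <- function(x, ...) {
  s <- x$training
  cat(sprintf("<trained_predictor> %s (%s, scope %s): CV MAE %.2f y, CV r %.3f%s\n",
              x$family, x$modality, x$scope,
              mean(s$fold_mae), mean(s$fold_r),
              if (!is.null(s$selected_epoch) && !is.na(s$selected_epoch))
                sprintf(", epoch %d", s$selected_epoch) else ""))
  invisible(x)
}

#' Predict age from features
#'
#' Applies a trained predictor to new subjects. Inference is deterministic
#' (dropout disabled); batch order is preserved.
#'
#' @param model A `trained_predictor`.
#' @param features Features in the same container and shape used at
#'   training time.
#' @return Numeric vector of predicted ages in years.
#' @export
predict_age <- function(model, features) {
  stopifnot(inherits(model, "trained_predictor"))
  chk <- check_model_inputs(features, model$family)
  if (!identical(as.integer(chk$shape), as.integer(model$input_shape)))
    stop("feature shape mismatch: expected ",
         paste(model$input_shape, collapse = "x"), ", got ",
         paste(chk$shape, collapse = "x"))
  raw <- switch(model$family,
    ridge = ridge_predict(model, chk$inputs),
    graph_conv = gcn_predict(model$params, chk$inputs),
    bilstm = lstm_predict(model$params, chk$inputs))
  out <- raw * model$y_scale + model$y_center
  if (any(!is.finite(out))) stop("non-finite prediction produced")
  unname(out)
}

#' Train one brain-age model per functional network
#'
#' Builds the per-network ("sub-network") predictors: for each network in
#' the atlas with at least two components, a model of the requested family
#' is trained on that network's within-network connectivity features only.
#'
#' @param fncs List of per-subject `static_fnc` (for `sfnc`) or
#'   `dynamic_fnc` (for `dfnc`) objects.
#' @param ages Chronological ages in years.
#' @param atlas A `component_atlas`.
#' @param spec A [model_spec()]; for `dfnc` use the `bilstm` family (or
#'   `ridge` on window-mean features).
#' @param train_cfg A [training_config()].
#' @param modality `"sfnc"` or `"dfnc"`.
#' @param subject_ids Optional subject grouping for folds.
#' @return Named list: one `trained_predictor` per network (networks with
#'   fewer than 2 components are skipped with a warning).
#' @export
build_subnetwork_models <- function(fncs, ages, atlas, spec,
                                    train_cfg = training_config(),
                                    modality = c("sfnc", "dfnc"),
                                    subject_ids = NULL) {
  modality <- match.arg(modality)
  out <- list()
  for (net in atlas_networks(atlas)) {
    comps <- network_components(atlas, net)
    if (length(comps) < 2L) {
      warning("network ", net, " has fewer than 2 components; skipped")
      next
    }
    feats <- subnetwork_features(fncs, atlas, net, spec$family)
    out[[net]] <- train_predictor(feats, ages, spec, train_cfg,
                                  subject_ids = subject_ids,
                                  scope = net, modality = modality)
  }
  out
}

## internal: extract the per-network feature container for a model family
subnetwork_features <- function(fncs, atlas, network, family) {
  blocks <- lapply(fncs, subnetwork_block, atlas = atlas, network = network)
  if (family == "ridge") {
    if (!is.null(blocks[[1]]$matrix))
      do.call(rbind, lapply(blocks, `[[`, "features"))
    else  # dynamic input for ridge: average the window features
      do.call(rbind, lapply(blocks, function(b) colMeans(b$features)))
  } else if (family == "graph_conv") {
    lapply(blocks, `[[`, "matrix")
  } else {
    lapply(blocks, `[[`, "features")
  }
}

#' Reduce dynamic-FNC sequences to their most variable edges
#'
#' Keeps the `k` edges whose window-averaged connectivity varies most across
#' subjects — a simple, deterministic feature reduction that keeps recurrent
#' training tractable at small scale.
#'
#' @param seqs List of T x p window-feature matrices (one per subject).
#' @param k Number of edges to keep.
#' @return List with `seqs` (reduced list of T x k matrices) and `keep`
#'   (the selected column indices).
#' @export
reduce_dfnc_features <- function(seqs, k = 50) {
  means <- do.call(rbind, lapply(seqs, colMeans))
  v <- apply(means, 2L, stats::var)
  keep <- order(v, decreasing = TRUE)[seq_len(min(k, length(v)))]
  keep <- sort(keep)
  list(seqs = lapply(seqs, function(s) s[, keep, drop = FALSE]), keep = keep)
}
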