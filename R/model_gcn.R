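## Graph-convolutional regressor on static FNC.
##
## For each subject the C x C connectivity matrix M provides both the graph
## and the node features: the propagation operator is A = row-normalized
## |M|, and the node feature matrix is X = M (each node described by its
## connectivity profile). Layers: H1 = relu(A X W1 + b1),
## H2 = relu(A H1 W2 + b2), global mean pooling over nodes, linear readout.
## Trained with Adam on MAE (standardized-age scale).

gcn_operator <- function(M) {
  A <- abs(M)
  A / rowSums(A)
}

gcn_init <- function(spec, shape) {
  C <- shape[1]
  d1 <- spec$graph_layer_sizes[1]
  d2 <- if (length(spec$graph_layer_sizes) >= 2)
    spec$graph_layer_sizes[2] else spec$graph_layer_sizes[1]
  list(W1 = glorot(C, d1), b1 = rep(0, d1),
       W2 = glorot(d1, d2), b2 = rep(0, d2),
       w3 = glorot(d2, 1), b3 = matrix(0, 1, 1))
}

gcn_forward_one <- function(params, M) {
  A <- gcn_operator(M)
  AX <- A %*% M
  Z1 <- sweep(AX %*% params$W1, 2L, params$b1, "+")
  H1 <- pmax(Z1, 0)
  AH1 <- A %*% H1
  Z2 <- sweep(AH1 %*% params$W2, 2L, params$b2, "+")
  H2 <- pmax(Z2, 0)
  h <- colMeans(H2)
  yhat <- sum(h * params$w3) + params$b3[1, 1]
  list(yhat = yhat, A = A, AX = AX, Z1 = Z1, H1 = H1, AH1 = AH1,
       Z2 = Z2, H2 = H2, h = h)
}

gcn_predict <- function(params, inputs) {
  vapply(inputs, function(M) gcn_forward_one(params, M)$yhat, numeric(1))
}

## MAE loss and gradients over a minibatch (list of matrices)
gcn_loss_grad <- function(params, inputs, y, spec) {
  n <- length(inputs)
  grads <- lapply(params, function(p) p * 0)
  loss <- 0
  C <- nrow(inputs[[1]])
  for (i in seq_len(n)) {
    fw <- gcn_forward_one(params, inputs[[i]])
    res <- fw$yhat - y[i]
    loss <- loss + abs(res)
    g <- sign(res) / n                     # dL/dyhat
    grads$w3 <- grads$w3 + g * fw$h
    grads$b3 <- grads$b3 + g
    dh <- g * drop(params$w3)              # length d2
    dH2 <- matrix(dh / C, C, length(dh), byrow = TRUE)
    dZ2 <- dH2 * (fw$Z2 > 0)
    grads$W2 <- grads$W2 + crossprod(fw$AH1, dZ2)
    grads$b2 <- grads$b2 + colSums(dZ2)
    dH1 <- crossprod(fw$A, dZ2) %*% t(params$W2)
    dZ1 <- dH1 * (fw$Z1 > 0)
    grads$W1 <- grads$W1 + crossprod(fw$AX, dZ1)
    grads$b1 <- grads$b1 + colSums(dZ1)
  }
  list(loss = loss / n, grads = grads)
}
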