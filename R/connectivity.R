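#' Pearson correlation between two component time courses
#'
#' The elementary connectivity measure: the sample Pearson correlation
#' \deqn{R = \frac{\sum_n (x_1 - \bar x_1)(x_2 - \bar x_2)}
#'   {\sqrt{\sum_n (x_1-\bar x_1)^2 \sum_n (x_2-\bar x_2)^2}}}
#' between two equal-length signals.
#'
#' @param x1,x2 Numeric vectors of equal length (>= 3), neither constant.
#' @param name1,name2 Labels used in error messages.
#' @return Correlation in `[-1, 1]`.
#' @export
pearson_correlation <- function(x1, x2, name1 = "x1", name2 = "x2") {
  if (length(x1) != length(x2)) stop("signals must have equal length")
  if (length(x1) < 3L) stop("signals must have length >= 3")
  for (nm in c(name1, name2)) {
    v <- if (nm == name1) x1 else x2
    if (stats::sd(v) == 0)
      stop("zero-variance (constant) component: ", nm)
  }
  r <- stats::cor(x1, x2)
  min(1, max(-1, r))
}

#' Static functional network connectivity
#'
#' Computes the full-scan correlation matrix between all pairs of components
#' (sFNC): entry (i, j) is the Pearson correlation of components i and j over
#' the whole scan. With the standard 53-component decomposition this is the
#' 53 x 53 connectivity matrix.
#'
#' @param ts A `timecourse_matrix` of prepared component signals.
#' @return An object of class `static_fnc`: list with `matrix` (C x C,
#'   symmetric, unit diagonal, labeled by component ids) and `subject_id`.
#' @export
static_fnc <- function(ts) {
  assert_timecourse(ts)
  sds <- apply(ts$data, 2, stats::sd)
  if (any(sds == 0))
    stop("zero-variance (constant) component: ",
         paste(ts$component_ids[sds == 0], collapse = ", "))
  m <- stats::cor(ts$data)
  m[m > 1] <- 1; m[m < -1] <- -1
  diag(m) <- 1
  structure(list(matrix = m, subject_id = ts$subject_id),
            class = "static_fnc")
}

## internal: accept either a static_fnc or a bare matrix
fnc_matrix <- function(fnc) {
  if (inherits(fnc, "static_fnc")) fnc$matrix else as.matrix(fnc)
}

#' Vectorize a connectivity matrix into its unique features
#'
#' Extracts the strict upper triangle of a symmetric C x C matrix in
#' row-major order — the canonical feature vector of C(C-1)/2 unique
#' connectivity values (1378 for C = 53).
#'
#' @param fnc A `static_fnc`, one dynamic-FNC slice, or a symmetric matrix.
#' @return Numeric vector of length `C*(C-1)/2`, named `i|j` by component
#'   pair when the matrix has dimnames.
#' @seealso [devectorize_fnc()]
#' @export
vectorize_fnc <- function(fnc) {
  m <- fnc_matrix(fnc)
  if (nrow(m) != ncol(m)) stop("connectivity matrix must be square")
  tm <- t(m)
  v <- tm[lower.tri(tm)]           # row-major strict upper triangle of m
  if (!is.null(rownames(m))) {
    idx <- which(lower.tri(tm), arr.ind = TRUE)   # (j, i) with i < j
    names(v) <- paste(rownames(m)[idx[, 2L]], rownames(m)[idx[, 1L]],
                      sep = "|")
  }
  v
}

#' Restore a symmetric unit-diagonal matrix from its feature vector
#'
#' Inverse of [vectorize_fnc()].
#'
#' @param v Feature vector of length `C*(C-1)/2`.
#' @param diag_value Value placed on the diagonal (1 for correlations).
#' @return Symmetric C x C matrix.
#' @export
devectorize_fnc <- function(v, diag_value = 1) {
  p <- length(v)
  C <- (1 + sqrt(1 + 8 * p)) / 2
  if (abs(C - round(C)) > 1e-8)
    stop("vector length ", p, " is not C*(C-1)/2 for any integer C")
  C <- as.integer(round(C))
  m <- matrix(0, C, C)
  tm <- t(m)
  tm[lower.tri(tm)] <- v
  m <- t(tm)
  m <- m + t(m)
  diag(m) <- diag_value
  m
}

#' Tapered sliding-window specification
#'
#' Describes the window used for dynamic FNC: a rectangular window of
#' `width_tr` frames convolved with a Gaussian kernel of standard deviation
#' `gaussian_sigma` (in TR units), advanced by `stride_tr` frames per
#' placement. The taper derived from the defaults (width 20 TR, sigma 3)
#' has support 20 + 2*ceil(9) = 38 frames.
#'
#' @param width_tr Rectangle width in frames (>= 2).
#' @param gaussian_sigma Gaussian kernel SD in frames; `0` gives the
#'   untapered (uniform) rectangle.
#' @param stride_tr Frames between consecutive window placements (>= 1).
#' @return An object of class `window_spec` with the derived `weights`
#'   vector (non-negative, sums to 1) and its `support` length.
#' @export
window_spec <- function(width_tr = 20, gaussian_sigma = 3, stride_tr = 1) {
  if (width_tr < 2) stop("window width must be >= 2 frames")
  if (gaussian_sigma < 0) stop("gaussian_sigma must be >= 0")
  if (stride_tr < 1) stop("stride must be >= 1 frame")
  w <- make_tapered_window(width_tr, gaussian_sigma)
  structure(list(width_tr = as.integer(width_tr),
                 gaussian_sigma = gaussian_sigma,
                 stride_tr = as.integer(stride_tr),
                 weights = w, support = length(w)),
            class = "window_spec")
}

#' Taper weights: rectangle convolved with a truncated Gaussian
#'
#' Full discrete convolution of a rectangular window of length `width` with
#' a unit-area Gaussian kernel truncated at +/- 3 sigma (kernel length
#' `2*ceil(3*sigma) + 1`), normalized to sum to one. `sigma = 0` is the
#' delta-kernel limit: uniform weights `1/width`.
#'
#' @param width Rectangle length in frames.
#' @param sigma Gaussian SD in frames.
#' @return Symmetric non-negative weight vector summing to 1, of length
#'   `width + 2*ceil(3*sigma)`.
#' @export
make_tapered_window <- function(width, sigma = 3) {
  if (width < 2) stop("window width must be >= 2 frames")
  if (sigma == 0) return(rep(1 / width, width))
  h <- ceiling(3 * sigma)
  k <- exp(-((-h:h)^2) / (2 * sigma^2))
  k <- k / sum(k)
  rect <- rep(1, width)
  w <- stats::convolve(rect, rev(k), type = "open")
  w <- w / sum(w)
  w[w < 0] <- 0   # guard tiny negative FFT round-off
  w
}

#' Weighted Pearson correlation
#'
#' Correlation under observation weights: weighted covariance divided by the
#' product of weighted standard deviations. Reduces exactly to the ordinary
#' Pearson correlation under uniform weights; used to compute connectivity
#' within a tapered window, with the taper as the weight vector.
#'
#' @param x1,x2 Numeric vectors of equal length.
#' @param weights Non-negative weights summing to 1, same length.
#' @return Correlation in `[-1, 1]`.
#' @export
weighted_pearson <- function(x1, x2, weights) {
  n <- length(x1)
  if (length(x2) != n || length(weights) != n)
    stop("x1, x2 and weights must have equal length")
  if (any(weights < 0)) stop("weights must be non-negative")
  s <- sum(weights)
  if (abs(s - 1) > 1e-8) stop("weights must sum to 1")
  m1 <- sum(weights * x1); m2 <- sum(weights * x2)
  d1 <- x1 - m1; d2 <- x2 - m2
  v1 <- sum(weights * d1^2); v2 <- sum(weights * d2^2)
  if (v1 <= 0 || v2 <= 0)
    stop("zero weighted variance; cannot compute weighted correlation")
  r <- sum(weights * d1 * d2) / sqrt(v1 * v2)
  min(1, max(-1, r))
}

## internal: weighted correlation matrix of all columns of X
weighted_corr_matrix <- function(X, weights) {
  mu <- drop(crossprod(weights, X))          # weighted column means
  Xc <- sweep(X, 2L, mu, "-")
  S <- crossprod(Xc * weights, Xc)           # weighted covariance (sum w = 1)
  v <- diag(S)
  if (any(v <= 0)) {
    bad <- colnames(X)[v <= 0]
    stop("zero weighted variance in window for component: ",
         paste(bad, collapse = ", "))
  }
  m <- S / sqrt(tcrossprod(v))
  m[m > 1] <- 1; m[m < -1] <- -1
  diag(m) <- 1
  m
}

#' Dynamic functional network connectivity
#'
#' Tapered sliding-window connectivity: for every fully supported placement
#' of the taper along the scan, the weighted Pearson correlation between all
#' component pairs is computed within the window, producing a C x C x T
#' array whose T slices trace the temporal evolution of every edge. Only
#' placements where the whole taper fits inside the scan are used.
#'
#' @param ts A `timecourse_matrix`.
#' @param spec A [window_spec()].
#' @return An object of class `dynamic_fnc`: list with `array` (C x C x T),
#'   `window` (the spec), `subject_id` and `n_windows`.
#' @export
dynamic_fnc <- function(ts, spec = window_spec()) {
  assert_timecourse(ts)
  stopifnot(inherits(spec, "window_spec"))
  n <- frame_count(ts)
  L <- spec$support
  if (n < L)
    stop("scan too short for window: ", n, " frames < support ", L, " frames")
  Tn <- (n - L) %/% spec$stride_tr + 1L
  C <- ncol(ts$data)
  arr <- array(NA_real_, dim = c(C, C, Tn),
               dimnames = list(ts$component_ids, ts$component_ids, NULL))
  for (t in seq_len(Tn)) {
    i0 <- (t - 1L) * spec$stride_tr + 1L
    arr[, , t] <- weighted_corr_matrix(ts$data[i0:(i0 + L - 1L), , drop = FALSE],
                                       spec$weights)
  }
  structure(list(array = arr, window = spec, subject_id = ts$subject_id,
                 n_windows = Tn),
            class = "dynamic_fnc")
}

#' Vectorize every window of a dynamic FNC array
#'
#' @param dfnc A `dynamic_fnc`.
#' @return T x `C*(C-1)/2` matrix; row t is the feature vector of window t.
#' @export
vectorize_dfnc <- function(dfnc) {
  stopifnot(inherits(dfnc, "dynamic_fnc"))
  t(apply(dfnc$array, 3L, vectorize_fnc))
}

#' Restrict connectivity to one functional network
#'
#' Subsets a static or dynamic FNC object to the components of one network,
#' preserving component order, and returns the reduced matrix/array together
#' with its within-network feature vector(s).
#'
#' @param fnc A `static_fnc` or `dynamic_fnc`.
#' @param atlas A `component_atlas` covering the object's components.
#' @param network Network label to extract.
#' @return For static input: list with `matrix` (k x k) and `features`
#'   (length `k*(k-1)/2`). For dynamic input: list with `array` (k x k x T)
#'   and `features` (T x `k*(k-1)/2`).
#' @export
subnetwork_block <- function(fnc, atlas, network) {
  comps <- network_components(atlas, network)
  if (length(comps) < 2L)
    stop("network '", network, "' has fewer than 2 components")
  if (inherits(fnc, "static_fnc")) {
    keep <- intersect(rownames(fnc$matrix), comps)
    m <- fnc$matrix[keep, keep, drop = FALSE]
    list(matrix = m, features = vectorize_fnc(m))
  } else if (inherits(fnc, "dynamic_fnc")) {
    keep <- intersect(dimnames(fnc$array)[[1L]], comps)
    arr <- fnc$array[keep, keep, , drop = FALSE]
    list(array = arr, features = t(apply(arr, 3L, vectorize_fnc)))
  } else {
    stop("fnc must be a 'static_fnc' or 'dynamic_fnc' object")
  }
}

#' Indices of within-network features in the wide-brain feature vector
#'
#' Maps a network's within-network edges to their positions in the full
#' row-major upper-triangle vectorization, so that restricting then
#' vectorizing equals vectorizing then masking.
#'
#' @param component_ids Ordered component labels of the full matrix.
#' @param atlas A `component_atlas`.
#' @param network Network label.
#' @return Integer vector of feature indices.
#' @export
subnetwork_feature_indices <- function(component_ids, atlas, network) {
  comps <- network_components(atlas, network)
  C <- length(component_ids)
  member <- component_ids %in% comps
  idx <- integer(0); k <- 0L
  for (i in seq_len(C - 1L)) for (j in (i + 1L):C) {
    k <- k + 1L
    if (member[i] && member[j]) idx <- c(idx, k)
  }
  idx
}
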