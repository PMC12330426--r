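#' Preparation (denoising) configuration
#'
#' Settings for the post-ICA denoising chain applied to each component time
#' course, in the fixed order: polynomial detrending, optional nuisance
#' regression, robust outlier clipping, zero-phase low-pass filtering.
#'
#' @param detrend_orders Polynomial orders removed alongside the constant
#'   term (default linear, quadratic and cubic).
#' @param nuisance_regressors Optional frames x k numeric matrix (e.g.
#'   realignment parameters); `NULL` skips the regression step.
#' @param add_derivatives When regressors are supplied, also regress out
#'   their backward-difference temporal derivatives (first row zero).
#' @param outlier_mad_threshold Clipping threshold in scaled-MAD units.
#' @param lowpass_hz Low-pass cutoff in Hz; must lie below the Nyquist
#'   frequency `1/(2*TR)` of every processed scan.
#' @param filter_order Butterworth filter order.
#' @return A `prep_config` list.
#' @export
prep_config <- function(detrend_orders = c(1, 2, 3),
                        nuisance_regressors = NULL,
                        add_derivatives = TRUE,
                        outlier_mad_threshold = 3.5,
                        lowpass_hz = 0.15,
                        filter_order = 5) {
  stopifnot(outlier_mad_threshold > 0, lowpass_hz > 0, filter_order >= 1)
  structure(list(detrend_orders = sort(unique(as.integer(detrend_orders))),
                 nuisance_regressors = nuisance_regressors,
                 add_derivatives = isTRUE(add_derivatives),
                 outlier_mad_threshold = outlier_mad_threshold,
                 lowpass_hz = lowpass_hz,
                 filter_order = as.integer(filter_order)),
            class = "prep_config")
}

#' Remove polynomial trends from each component
#'
#' Least-squares projection of each component onto a polynomial basis
#' (constant plus the requested orders of normalized time on `[-1, 1]`) is
#' subtracted, leaving residuals with zero mean and no trend up to the
#' highest requested order.
#'
#' @param ts A `timecourse_matrix`.
#' @param orders Polynomial orders to remove (the constant is always
#'   included).
#' @return Detrended `timecourse_matrix`.
#' @export
detrend_polynomial <- function(ts, orders = c(1, 2, 3)) {
  assert_timecourse(ts)
  n <- frame_count(ts)
  orders <- sort(unique(as.integer(orders)))
  if (max(orders) >= n - 1L)
    stop("too few frames (", n, ") for polynomial order ", max(orders))
  tt <- seq(-1, 1, length.out = n)
  X <- cbind(1, sapply(orders, function(o) tt^o))
  qr_x <- qr(X)
  resid <- ts$data - X %*% qr.coef(qr_x, ts$data)
  tc_replace(ts, resid)
}

#' Regress nuisance signals out of each component
#'
#' Ordinary least-squares residualization of every component on an intercept
#' plus the supplied regressors (optionally augmented with their backward-
#' difference temporal derivatives, first row zero). Residuals are
#' orthogonal to every regressor.
#'
#' @param ts A `timecourse_matrix`.
#' @param regressors frames x k numeric matrix.
#' @param add_derivatives Append temporal derivatives of the regressors.
#' @return Residual `timecourse_matrix`.
#' @export
regress_nuisance <- function(ts, regressors, add_derivatives = FALSE) {
  assert_timecourse(ts)
  R <- as.matrix(regressors)
  n <- frame_count(ts)
  if (nrow(R) != n)
    stop("regressors have ", nrow(R), " rows but the scan has ", n, " frames")
  if (is.null(colnames(R))) colnames(R) <- paste0("reg", seq_len(ncol(R)))
  if (add_derivatives) {
    D <- rbind(0, diff(R))
    colnames(D) <- paste0("d_", colnames(R))
    R <- cbind(R, D)
  }
  X <- cbind(intercept = 1, R)
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    dropped <- colnames(X)[qr_x$pivot[(qr_x$rank + 1L):ncol(X)]]
    stop("nuisance design is rank deficient; collinear columns: ",
         paste(dropped, collapse = ", "))
  }
  resid <- ts$data - X %*% qr.coef(qr_x, ts$data)
  tc_replace(ts, resid)
}

#' Clip outlier frames per component (robust despiking)
#'
#' Values farther than `mad_threshold` scaled MADs (1.4826 x median absolute
#' deviation) from the component median are clipped to the nearest bound;
#' all other values are untouched. A component with zero MAD is passed
#' through unchanged with a warning.
#'
#' @param ts A `timecourse_matrix`.
#' @param mad_threshold Positive threshold in scaled-MAD units.
#' @return Clipped `timecourse_matrix`.
#' @export
remove_outliers <- function(ts, mad_threshold = 3.5) {
  assert_timecourse(ts)
  if (mad_threshold <= 0) stop("mad_threshold must be positive")
  out <- ts$data
  for (j in seq_len(ncol(out))) {
    x <- out[, j]
    med <- stats::median(x)
    s <- stats::mad(x, center = med)   # 1.4826 * median |x - med|
    if (s == 0) {
      warning("component ", ts$component_ids[j],
              " has zero MAD; outlier clipping skipped")
      next
    }
    lo <- med - mad_threshold * s
    hi <- med + mad_threshold * s
    out[, j] <- pmin(pmax(x, lo), hi)
  }
  tc_replace(ts, out)
}

## internal: steady-state initial filter state (direct form II transposed),
## so that filtering a constant produces no startup transient
lfilter_zi <- function(b, a) {
  n <- max(length(a), length(b))
  b <- c(b, rep(0, n - length(b)))
  a <- c(a, rep(0, n - length(a)))
  b <- b / a[1]; a <- a / a[1]
  comp <- rbind(-a[2:n], cbind(diag(n - 2L), rep(0, n - 2L)))
  solve(diag(n - 1L) - t(comp), b[2:n] - a[2:n] * b[1])
}

## internal: IIR filter with explicit initial state (direct form II
## transposed), matching the conventional lfilter recursion
lfilter <- function(b, a, x, zi) {
  n <- max(length(a), length(b))
  b <- c(b, rep(0, n - length(b)))
  a <- c(a, rep(0, n - length(a)))
  b <- b / a[1]; a <- a / a[1]
  nz <- n - 1L
  z <- zi
  y <- numeric(length(x))
  for (m in seq_along(x)) {
    xm <- x[m]
    ym <- b[1L] * xm + z[1L]
    if (nz > 1L)
      z[1L:(nz - 1L)] <- b[2L:nz] * xm + z[2L:nz] - a[2L:nz] * ym
    z[nz] <- b[n] * xm - a[n] * ym
    y[m] <- ym
  }
  y
}

## internal: zero-phase Butterworth low-pass of one signal.
## Odd-symmetric edge padding of length 3*order, forward and backward pass,
## each pass started from its steady state scaled to the first sample.
butter_filtfilt <- function(x, b, a, pad) {
  n <- length(x)
  pad <- min(pad, n - 1L)
  ext <- c(2 * x[1L] - x[(pad + 1L):2L], x, 2 * x[n] - x[(n - 1L):(n - pad)])
  zi <- lfilter_zi(b, a)
  y <- lfilter(b, a, ext, zi * ext[1L])
  y <- rev(y)
  y <- lfilter(b, a, y, zi * y[1L])
  y <- rev(y)
  y[(pad + 1L):(pad + n)]
}

#' Zero-phase low-pass filter
#'
#' Butterworth low-pass applied forward and backward (zero phase) to every
#' component, with odd-symmetric edge padding of length `3*order`. The
#' default 0.15 Hz cutoff retains the slow fluctuations that carry
#' functional connectivity while suppressing high-frequency noise.
#'
#' @param ts A `timecourse_matrix`.
#' @param cutoff_hz Cutoff frequency in Hz, strictly below Nyquist.
#' @param order Butterworth order (per pass).
#' @return Filtered `timecourse_matrix`.
#' @export
lowpass_filter <- function(ts, cutoff_hz = 0.15, order = 5) {
  assert_timecourse(ts)
  nyq <- 1 / (2 * ts$tr_seconds)
  if (cutoff_hz >= nyq)
    stop(sprintf("cutoff %.3f Hz is at/above Nyquist %.3f Hz (TR %.3f s)",
                 cutoff_hz, nyq, ts$tr_seconds))
  bf <- signal::butter(order, cutoff_hz / nyq, type = "low")
  pad <- 3L * as.integer(order)
  out <- apply(ts$data, 2L, butter_filtfilt, b = bf$b, a = bf$a, pad = pad)
  tc_replace(ts, out)
}

#' Truncate scans to the shortest common duration
#'
#' Harmonizes scan durations across acquisitions with heterogeneous
#' repetition times: the common duration is the minimum of
#' `frames * TR` over all scans, and each scan keeps its first
#' `floor(common_duration / TR)` frames in its native sampling (no
#' resampling across TRs).
#'
#' @param scans Non-empty list of `timecourse_matrix` objects.
#' @return List with `scans` (truncated list) and
#'   `common_duration_seconds`.
#' @export
truncate_to_common_duration <- function(scans) {
  if (length(scans) == 0L) stop("scan list is empty")
  durations <- vapply(scans, function(s) frame_count(s) * s$tr_seconds,
                      numeric(1))
  common <- min(durations)
  out <- lapply(scans, function(s) {
    keep <- floor(common / s$tr_seconds)
    tc_replace(s, s$data[seq_len(keep), , drop = FALSE])
  })
  list(scans = out, common_duration_seconds = common)
}

#' Run the full denoising chain on one scan
#'
#' Applies, in order: polynomial detrending, nuisance regression (when
#' regressors are configured), robust outlier clipping, zero-phase low-pass
#' filtering.
#'
#' @param ts A `timecourse_matrix`.
#' @param config A [prep_config()].
#' @return Prepared `timecourse_matrix`.
#' @export
prep_timecourses <- function(ts, config = prep_config()) {
  stopifnot(inherits(config, "prep_config"))
  out <- detrend_polynomial(ts, config$detrend_orders)
  if (!is.null(config$nuisance_regressors))
    out <- regress_nuisance(out, config$nuisance_regressors,
                            add_derivatives = config$add_derivatives)
  out <- remove_outliers(out, config$outlier_mad_threshold)
  lowpass_filter(out, config$lowpass_hz, config$filter_order)
}
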