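test_that("pearson_correlation matches the defining sums and its invariances", {
  x1 <- c(1, 2, 3, 4); x2 <- c(1, 3, 2, 5)
  expect_equal(pearson_correlation(x1, x2), oracle_pearson(x1, x2),
               tolerance = 1e-14)
  expect_equal(pearson_correlation(x1, x1), 1)
  expect_equal(pearson_correlation(x1, -x1), -1)
  # invariance to positive affine rescaling
  expect_equal(pearson_correlation(2.5 * x1 + 7, x2),
               pearson_correlation(x1, x2), tolerance = 1e-12)
  expect_error(pearson_correlation(rep(1, 5), 1:5), "zero-variance")
  expect_error(pearson_correlation(1:4, 1:5), "equal length")
})

test_that("static_fnc equals a brute-force pairwise loop", {
  ts <- rand_timecourse(500, 5, seed = 3)
  s <- static_fnc(ts)
  C <- 5
  for (i in 1:C) for (j in 1:C) {
    want <- if (i == j) 1 else oracle_pearson(ts$data[, i], ts$data[, j])
    expect_equal(s$matrix[i, j], want, tolerance = 1e-12)
  }
  expect_equal(s$matrix, t(s$matrix))
  # perfectly correlated pair
  ts2 <- timecourse_matrix(cbind(a = 1:50, b = 2 * (1:50) + 3), 1)
  expect_equal(static_fnc(ts2)$matrix[1, 2], 1)
  # constant component named in the error
  ts3 <- timecourse_matrix(cbind(ok = rnorm(20), flat = rep(2, 20)), 1)
  expect_error(static_fnc(ts3), "flat")
})

test_that("vectorization is row-major upper triangle and inverts exactly", {
  expect_length(vectorize_fnc(diag(53)), 1378)
  expect_length(vectorize_fnc(diag(4)), 6)
  # row-major order: (1,2),(1,3),(1,4),(2,3),(2,4),(3,4)
  m <- matrix(0, 4, 4)
  for (i in 1:4) for (j in 1:4) m[i, j] <- 10 * min(i, j) + max(i, j)
  expect_equal(unname(vectorize_fnc(m)), c(12, 13, 14, 23, 24, 34))
  # round trip on a random symmetric matrix
  s <- rand_corr(7, seed = 5)
  expect_identical(devectorize_fnc(vectorize_fnc(s)), unname(s))
  expect_error(vectorize_fnc(matrix(1, 2, 3)), "square")
  expect_error(devectorize_fnc(1:4), "C")
})

test_that("taper weights match a direct convolution oracle", {
  w <- make_tapered_window(20, 3)
  expect_length(w, 38)                      # 20 + 2*ceil(9)
  expect_equal(sum(w), 1, tolerance = 1e-12)
  expect_equal(w, rev(w), tolerance = 1e-12)
  h <- 9
  k <- exp(-((-h:h)^2) / 18); k <- k / sum(k)
  want <- oracle_convolve(rep(1, 20), k)
  expect_equal(w, want / sum(want), tolerance = 1e-12)
  # delta-kernel limit: uniform weights
  expect_equal(make_tapered_window(15, 0), rep(1 / 15, 15))
  # normalization holds for any spec
  for (width in c(2, 7, 40)) for (sig in c(0.5, 2, 4))
    expect_equal(sum(make_tapered_window(width, sig)), 1, tolerance = 1e-12)
})

test_that("weighted_pearson reduces to Pearson and matches the moment oracle", {
  set.seed(8)
  x1 <- rnorm(40); x2 <- rnorm(40)
  u <- rep(1 / 40, 40)
  expect_equal(weighted_pearson(x1, x2, u), pearson_correlation(x1, x2),
               tolerance = 1e-12)
  w <- make_tapered_window(22, 3)
  x1 <- rnorm(length(w)); x2 <- rnorm(length(w))
  expect_equal(weighted_pearson(x1, x2, w),
               oracle_weighted_pearson(x1, x2, w), tolerance = 1e-12)
  # weights concentrated on two points give |R| = 1
  w2 <- c(0.5, 0.5, rep(0, length(x1) - 2))
  expect_equal(abs(weighted_pearson(x1, x2, w2)), 1, tolerance = 1e-12)
  expect_error(weighted_pearson(x1, x2, w * 2), "sum to 1")
  expect_error(weighted_pearson(rep(1, 5), rnorm(5), rep(0.2, 5)),
               "weighted variance")
})

test_that("dynamic_fnc matches per-window brute-force recomputation", {
  ts <- rand_timecourse(160, 4, seed = 11)
  spec <- window_spec(20, 3, stride_tr = 5)
  d <- dynamic_fnc(ts, spec)
  L <- spec$support
  expect_equal(d$n_windows, (160 - L) %/% 5 + 1)
  for (t in seq_len(d$n_windows)) {
    i0 <- (t - 1) * 5 + 1
    win <- ts$data[i0:(i0 + L - 1), ]
    for (i in 1:4) for (j in 1:4) {
      want <- if (i == j) 1 else
        oracle_weighted_pearson(win[, i], win[, j], spec$weights)
      expect_equal(d$array[i, j, t], want, tolerance = 1e-12)
    }
    sl <- d$array[, , t]
    expect_equal(sl, t(sl), tolerance = 1e-12)
    expect_true(all(sl >= -1 & sl <= 1))
  }
})

test_that("full-scan uniform window reproduces static FNC exactly", {
  ts <- rand_timecourse(90, 5, seed = 13)
  d <- dynamic_fnc(ts, window_spec(90, 0, 1))
  expect_equal(d$n_windows, 1L)
  expect_equal(d$array[, , 1], static_fnc(ts)$matrix, tolerance = 1e-12)
})

test_that("windowed estimates average to the static value on stationary data", {
  set.seed(21)
  R <- rand_corr(4)
  X <- matrix(rnorm(8000 * 4), 8000) %*% chol(R)
  ts <- timecourse_matrix(X, 0.72)
  d <- dynamic_fnc(ts, window_spec(20, 3, stride_tr = 20))
  mean_edges <- apply(d$array, c(1, 2), mean)
  expect_lt(max(abs(mean_edges - static_fnc(ts)$matrix)), 0.05)
})

test_that("a planted state switch moves the edge trajectory", {
  set.seed(22)
  n <- 300; sw <- 150
  R1 <- diag(2); R1[1, 2] <- R1[2, 1] <- 0.8
  R2 <- diag(2); R2[1, 2] <- R2[2, 1] <- -0.8
  X <- rbind(matrix(rnorm(sw * 2), sw) %*% chol(R1),
             matrix(rnorm((n - sw) * 2), n - sw) %*% chol(R2))
  d <- dynamic_fnc(timecourse_matrix(X, 1), window_spec(20, 3, 1))
  edge <- d$array[1, 2, ]
  expect_gt(mean(edge[1:80]), 0.5)
  expect_lt(mean(edge[(length(edge) - 80):length(edge)]), -0.5)
})

test_that("scans shorter than the window support are rejected informatively", {
  ts <- rand_timecourse(30, 3, seed = 2)
  err <- expect_error(dynamic_fnc(ts, window_spec(20, 3)), "30")
  expect_match(conditionMessage(err), "38")
})

test_that("sub-network blocks partition the wide-brain features", {
  atlas <- component_atlas()
  C <- nrow(atlas)
  within <- unlist(lapply(atlas_networks(atlas), function(net)
    subnetwork_feature_indices(atlas$component_id, atlas, net)))
  expect_false(anyDuplicated(within) > 0)
  n_within <- length(within)
  n_between <- C * (C - 1) / 2 - n_within
  expect_equal(n_within + n_between, 1378)
  # restricting then vectorizing equals vectorizing then masking
  m <- rand_corr(C)
  dimnames(m) <- list(atlas$component_id, atlas$component_id)
  s <- structure(list(matrix = m, subject_id = "S1"), class = "static_fnc")
  v <- vectorize_fnc(m)
  for (net in c("SCN", "AUD", "CBN")) {
    idx <- subnetwork_feature_indices(atlas$component_id, atlas, net)
    expect_equal(unname(subnetwork_block(s, atlas, net)$features),
                 unname(v[idx]))
  }
  # two-component network yields a single feature
  expect_length(subnetwork_block(s, atlas, "AUD")$features, 1)
  expect_error(subnetwork_block(s, atlas, "XXX"), "SCN")
})
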