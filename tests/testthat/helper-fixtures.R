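# Shared fixtures, all generated in code.

# a random correlation matrix with unit diagonal
rand_corr <- function(C, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  W <- matrix(rnorm(C * C), C)
  m <- stats::cov2cor(tcrossprod(W) + diag(C) * C)
  m <- (m + t(m)) / 2   # exact symmetry
  dimnames(m) <- list(paste0("IC", 1:C), paste0("IC", 1:C))
  m
}

# a small Gaussian time-course matrix
rand_timecourse <- function(frames = 120, C = 5, tr = 0.72, seed = 1,
                            subject_id = "S1") {
  set.seed(seed)
  timecourse_matrix(matrix(rnorm(frames * C), frames, C), tr, subject_id)
}

# small cohort configuration used across tests
tiny_cohort_config <- function(...) {
  args <- utils::modifyList(
    list(n_subjects = 8, n_components = 6, n_frames = 100,
         tr_seconds = 0.72, n_states = 2, state_dwell_mean = 20, seed = 42),
    list(...))
  do.call(cohort_config, args)
}

# brute-force Pearson correlation straight from the defining sums
oracle_pearson <- function(x1, x2) {
  d1 <- x1 - mean(x1); d2 <- x2 - mean(x2)
  sum(d1 * d2) / sqrt(sum(d1^2) * sum(d2^2))
}

# brute-force weighted correlation from explicit weighted moments
oracle_weighted_pearson <- function(x1, x2, w) {
  m1 <- sum(w * x1); m2 <- sum(w * x2)
  cv <- sum(w * (x1 - m1) * (x2 - m2))
  cv / sqrt(sum(w * (x1 - m1)^2) * sum(w * (x2 - m2)^2))
}

# direct discrete full convolution (double loop)
oracle_convolve <- function(a, b) {
  n <- length(a) + length(b) - 1L
  out <- numeric(n)
  for (i in seq_along(a)) for (j in seq_along(b))
    out[i + j - 1L] <- out[i + j - 1L] + a[i] * b[j]
  out
}

# hand-applied Benjamini-Hochberg step-up rule
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  prev <- 1
  for (k in m:1) {
    val <- min(prev, p[o[k]] * m / k)
    adj[o[k]] <- val
    prev <- val
  }
  adj
}

# a cheap synthetic bag table for association tests (no imaging involved)
synth_bag_table <- function(n = 160, slope = 0, scope = "wide",
                            modality = "sfnc", seed = NULL,
                            noise_sd = 4, bag_sd = 3) {
  if (!is.null(seed)) set.seed(seed)
  d <- data.frame(
    subject_id = sprintf("S%04d", 1:n),
    age = runif(n, 40, 60),
    predicted_age = 0,
    sex = sample(c("F", "M"), n, replace = TRUE),
    site = sample(1:3, n, replace = TRUE),
    diagnosis = rbinom(n, 1, 0.5),
    bag = rnorm(n, sd = bag_sd))
  d$predicted_age <- d$age + d$bag
  d$attention <- slope * d$bag + rnorm(n, sd = noise_sd)
  d$working_memory <- slope * d$bag + rnorm(n, sd = noise_sd)
  d$scope <- scope
  d$modality <- modality
  class(d) <- c("bag_table", "data.frame")
  d
}
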