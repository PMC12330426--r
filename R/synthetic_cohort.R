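#' Synthetic cohort configuration
#'
#' Parameters of the synthetic resting-state cohort generator. The generator
#' emulates the structure that functional brain-age models exploit:
#' age-dependent inter-component covariance on a fixed random subset of
#' edges, temporally switching connectivity states, site-wise mean shifts, a
#' diagnosis-linked aging acceleration, subject-level idiosyncratic aging,
#' and cognition scores negatively coupled to true brain-age acceleration.
#'
#' @param n_subjects Number of subjects.
#' @param n_components Number of components per scan (>= 2; 53 matches the
#'   standard decomposition).
#' @param n_frames Frames per scan.
#' @param tr_seconds Repetition time in seconds.
#' @param age_range Chronological age range in years, `c(min, max)`.
#' @param aging_edge_fraction Fraction of edges carrying age signal.
#' @param aging_slope Correlation units per year of effective age on
#'   affected edges.
#' @param n_states Number of connectivity states.
#' @param state_dwell_mean Mean state dwell time in frames.
#' @param state_delta Magnitude of the per-state +/- offset on affected
#'   edges (correlation units).
#' @param site_count Number of acquisition sites.
#' @param site_shift_sd SD of the per-site per-component mean shift
#'   (signal units).
#' @param diagnosis_fraction Fraction of subjects carrying the diagnosis.
#' @param diagnosis_bag_shift Years of planted aging acceleration in
#'   diagnosed subjects.
#' @param bag_noise_sd SD (years) of subject-level idiosyncratic aging
#'   acceleration; gives every subject a continuous true brain-age gap so
#'   BAG-cognition coupling survives diagnosis adjustment.
#' @param cognition_slope Score units per year of true brain-age gap
#'   (negative: accelerated aging lowers performance).
#' @param cognition_noise_sd SD of the cognition score noise.
#' @param seed Integer seed; identical configs reproduce cohorts exactly.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_subjects = 150,
                          n_components = 53,
                          n_frames = 490,
                          tr_seconds = 0.735,
                          age_range = c(22, 100),
                          aging_edge_fraction = 0.15,
                          aging_slope = 0.003,
                          n_states = 3,
                          state_dwell_mean = 40,
                          state_delta = 0.2,
                          site_count = 3,
                          site_shift_sd = 0.1,
                          diagnosis_fraction = 0,
                          diagnosis_bag_shift = 7,
                          bag_noise_sd = 5,
                          cognition_slope = -0.5,
                          cognition_noise_sd = 4,
                          seed = 1L) {
  stopifnot(n_components >= 2, n_subjects >= 1, n_frames >= 2,
            tr_seconds > 0, length(age_range) == 2,
            age_range[1] < age_range[2],
            aging_edge_fraction >= 0, aging_edge_fraction <= 1,
            diagnosis_fraction >= 0, diagnosis_fraction <= 1,
            n_states >= 1, state_dwell_mean >= 1, state_delta >= 0,
            site_count >= 1, site_shift_sd >= 0, bag_noise_sd >= 0,
            cognition_noise_sd >= 0, is.finite(cognition_slope))
  structure(as.list(environment()), class = "cohort_config")
}

## internal: nearest-PSD repair by eigenvalue clipping at 0, then
## renormalization to unit diagonal. Deterministic.
psd_repair <- function(m, tol = 1e-8) {
  m <- (m + t(m)) / 2
  e <- eigen(m, symmetric = TRUE)
  if (min(e$values) >= -tol && all(abs(diag(m) - 1) < 1e-12)) return(m)
  vals <- pmax(e$values, 0)
  r <- e$vectors %*% (vals * t(e$vectors))
  d <- diag(r)
  if (any(d <= tol))
    stop("covariance not repairable to a valid correlation matrix; ",
         "reduce aging_slope or state_delta")
  r <- r / sqrt(tcrossprod(d))
  (r + t(r)) / 2
}

#' Age-modulated component covariance
#'
#' Adds the planted aging signal to a base correlation matrix:
#' `aging_slope * (effective_age - midpoint)` on the masked edges, then
#' projects to the nearest positive semi-definite matrix (eigenvalue
#' clipping at zero) with the unit diagonal restored. Deterministic in its
#' inputs.
#'
#' @param effective_age Effective (true brain) age in years.
#' @param config A [cohort_config()]; supplies `aging_slope` and the age
#'   midpoint.
#' @param edge_mask Symmetric logical matrix with zero diagonal marking the
#'   edges that carry age signal.
#' @param base_cov Symmetric PSD matrix with unit diagonal.
#' @return Symmetric PSD matrix with unit diagonal.
#' @export
build_age_covariance <- function(effective_age, config, edge_mask, base_cov) {
  if (max(abs(base_cov - t(base_cov))) > 1e-10)
    stop("base_cov must be symmetric")
  if (max(abs(edge_mask - t(edge_mask))) > 0 || any(diag(edge_mask) != 0))
    stop("edge_mask must be symmetric with zero diagonal")
  mid <- mean(config$age_range)
  m <- base_cov + config$aging_slope * (effective_age - mid) * (edge_mask != 0)
  m[m > 1] <- 1; m[m < -1] <- -1
  diag(m) <- 1
  psd_repair(m)
}

#' Sample a Markov state sequence
#'
#' First-order Markov chain over `n_states` connectivity states with
#' self-transition probability `1 - 1/dwell_mean` and uniform transitions to
#' the other states, giving geometric dwell times with the requested mean.
#'
#' @param n_frames Sequence length.
#' @param n_states Number of states (>= 1).
#' @param dwell_mean Mean dwell time in frames (>= 1).
#' @return Integer vector of state indices in `1..n_states`.
#' @export
sample_state_sequence <- function(n_frames, n_states, dwell_mean) {
  stopifnot(n_states >= 1, dwell_mean >= 1, n_frames >= 1)
  if (n_states == 1L) return(rep(1L, n_frames))
  p_stay <- 1 - 1 / dwell_mean
  s <- integer(n_frames)
  s[1L] <- sample.int(n_states, 1L)
  stay <- stats::runif(n_frames - 1L) < p_stay
  jumps <- sample.int(n_states - 1L, n_frames - 1L, replace = TRUE)
  for (t in 2L:n_frames) {
    if (stay[t - 1L]) {
      s[t] <- s[t - 1L]
    } else {
      j <- jumps[t - 1L]
      s[t] <- if (j >= s[t - 1L]) j + 1L else j
    }
  }
  s
}

## internal: draw the cohort-level shared structure from the current RNG
## state: base correlation matrix, aging edge mask, per-state offsets,
## per-site mean shifts.
draw_cohort_structure <- function(config) {
  C <- config$n_components
  W <- matrix(stats::rnorm(C * max(2L, C %/% 2L)), C)
  base <- stats::cov2cor(tcrossprod(W) + diag(C) * C)
  base <- psd_repair(base)
  n_edges <- C * (C - 1L) / 2L
  n_aging <- round(config$aging_edge_fraction * n_edges)
  edge_idx <- sample.int(n_edges, n_aging)
  mask_v <- rep(0, n_edges); mask_v[edge_idx] <- 1
  edge_mask <- devectorize_fnc(mask_v, diag_value = 0)
  state_offsets <- lapply(seq_len(config$n_states), function(s) {
    sign_v <- rep(0, n_edges)
    sign_v[edge_idx] <- sample(c(-1, 1), n_aging, replace = TRUE)
    devectorize_fnc(config$state_delta * sign_v, diag_value = 0)
  })
  site_shifts <- matrix(stats::rnorm(config$site_count * C,
                                     sd = config$site_shift_sd),
                        nrow = config$site_count)
  list(base_cov = base, edge_mask = edge_mask,
       state_offsets = state_offsets, site_shifts = site_shifts)
}

#' Generate one subject's component time courses
#'
#' Frames are drawn from a zero-mean multivariate normal whose covariance at
#' each frame is the state-specific, age-modulated correlation matrix for
#' the subject's effective age; the subject's site mean shift is then added.
#'
#' @param record One-row data frame with `age`, `site`, `subject_id` and
#'   `effective_age`.
#' @param config A [cohort_config()].
#' @param shared Shared cohort structure from the generator (base
#'   covariance, edge mask, state offsets, site shifts).
#' @return A `timecourse_matrix` (frames x components).
#' @export
generate_subject <- function(record, config, shared) {
  C <- config$n_components
  covs <- lapply(shared$state_offsets, function(off) {
    build_age_covariance(record$effective_age, config,
                         shared$edge_mask,
                         psd_repair(shared$base_cov + off))
  })
  chols <- lapply(covs, function(m) {
    ch <- tryCatch(chol(m + diag(C) * 1e-10),
                   error = function(e) stop("singular state covariance"))
    ch
  })
  states <- sample_state_sequence(config$n_frames, config$n_states,
                                  config$state_dwell_mean)
  Z <- matrix(stats::rnorm(config$n_frames * C), config$n_frames, C)
  X <- matrix(0, config$n_frames, C)
  for (s in unique(states)) {
    rows <- states == s
    X[rows, ] <- Z[rows, , drop = FALSE] %*% chols[[s]]
  }
  X <- sweep(X, 2L, shared$site_shifts[record$site, ], "+")
  timecourse_matrix(X, config$tr_seconds, record$subject_id,
                    paste0("IC", seq_len(C)))
}

#' Generate cognition scores from true brain-age gaps
#'
#' Each score equals `cognition_slope * true_bag` plus independent Gaussian
#' noise (intercept fixed at zero; scores are unit-free). Attention and
#' working memory receive independent noise draws.
#'
#' @param true_bag Vector of true brain-age gaps in years.
#' @param config A [cohort_config()].
#' @return Data frame with columns `attention` and `working_memory`.
#' @export
generate_cognition <- function(true_bag, config) {
  n <- length(true_bag)
  data.frame(
    attention = config$cognition_slope * true_bag +
      stats::rnorm(n, sd = config$cognition_noise_sd),
    working_memory = config$cognition_slope * true_bag +
      stats::rnorm(n, sd = config$cognition_noise_sd)
  )
}

#' Simulate a synthetic cohort
#'
#' Draws phenotypes (age uniform over the configured range, balanced sex,
#' uniform site, Bernoulli diagnosis), plants the true effective age
#' (chronological + diagnosis shift + idiosyncratic acceleration), generates
#' per-subject component time courses from the state-switching,
#' age-modulated covariance model and couples cognition scores to the true
#' brain-age gap. Fully reproducible from `config$seed`.
#'
#' @param config A [cohort_config()].
#' @param shared Optional shared structure from a previous cohort (to
#'   simulate a test cohort under the same connectivity model as a training
#'   cohort); drawn from the seed when `NULL`.
#' @return An object of class `synthetic_cohort`: list with `timecourses`
#'   (list of `timecourse_matrix`), `phenotypes` (data frame: subject_id,
#'   age, sex, site, diagnosis, attention, working_memory), `truth` (data
#'   frame: subject_id, effective_age, true_bag), `structure` and `config`.
#' @export
simulate_cohort <- function(config = cohort_config(), shared = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  if (is.null(shared)) shared <- draw_cohort_structure(config)
  n <- config$n_subjects
  pheno <- data.frame(
    subject_id = sprintf("S%04d", seq_len(n)),
    age = stats::runif(n, config$age_range[1], config$age_range[2]),
    sex = sample(c("F", "M"), n, replace = TRUE),
    site = sample.int(config$site_count, n, replace = TRUE),
    diagnosis = as.integer(stats::runif(n) < config$diagnosis_fraction),
    stringsAsFactors = FALSE
  )
  effective_age <- pheno$age +
    config$diagnosis_bag_shift * pheno$diagnosis +
    stats::rnorm(n, sd = config$bag_noise_sd)
  true_bag <- effective_age - pheno$age
  cog <- generate_cognition(true_bag, config)
  pheno$attention <- cog$attention
  pheno$working_memory <- cog$working_memory
  tcs <- vector("list", n)
  for (i in seq_len(n)) {
    rec <- data.frame(subject_id = pheno$subject_id[i], age = pheno$age[i],
                      site = pheno$site[i], effective_age = effective_age[i])
    tcs[[i]] <- generate_subject(rec, config, shared)
  }
  structure(list(timecourses = tcs, phenotypes = pheno,
                 truth = data.frame(subject_id = pheno$subject_id,
                                    effective_age = effective_age,
                                    true_bag = true_bag),
                 structure = shared, config = config),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("<synthetic_cohort> %d subjects, %d components x %d frames (TR %.3f s), %d states, %d sites, %.0f%% diagnosed\n",
              cfg$n_subjects, cfg$n_components, cfg$n_frames, cfg$tr_seconds,
              cfg$n_states, cfg$site_count, 100 * cfg$diagnosis_fraction))
  invisible(x)
}

#' Default atlas for a reduced synthetic cohort
#'
#' Assigns the cohort's components round-robin to the seven canonical
#' network labels (or fewer when there are few components), so sub-network
#' machinery is exercisable at any scale.
#'
#' @param n_components Number of components.
#' @param n_networks Number of networks (<= 7).
#' @return A `component_atlas`.
#' @export
synthetic_atlas <- function(n_components, n_networks = 7) {
  labels <- c("SCN", "AUD", "SMN", "VSN", "CCN", "DMN", "CBN")
  n_networks <- min(n_networks, length(labels), n_components %/% 2L)
  nets <- labels[rep_len(seq_len(n_networks), n_components)]
  make_atlas(paste0("IC", seq_len(n_components)), sort_networks(nets, labels))
}

## internal: keep canonical label order but group components contiguously
sort_networks <- function(nets, labels) {
  factor(nets, levels = labels[labels %in% nets])
}
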