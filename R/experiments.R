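#' Desk-scale recovery study configuration
#'
#' The fixed synthetic study conditions used to verify that every model
#' family recovers a planted linear aging signal: 400 subjects, 16
#' components, 200 frames at TR 0.72 s, aging slope 0.004 correlation units
#' per year on 15% of edges, three connectivity states. These conditions
#' were chosen once, from the sampling error of a correlation estimated
#' from ~200 frames relative to the planted across-subject signal, to put a
#' linear readout in the same accuracy regime (validation r around 0.9) as
#' full-scale functional brain-age models.
#'
#' @param seed Integer seed.
#' @param n_subjects,n_components,n_frames Override the study size.
#' @return A [cohort_config()].
#' @export
recovery_cohort_config <- function(seed, n_subjects = 400,
                                   n_components = 16, n_frames = 200) {
  cohort_config(n_subjects = n_subjects, n_components = n_components,
                n_frames = n_frames, tr_seconds = 0.72,
                aging_slope = 0.004, n_states = 3, state_dwell_mean = 40,
                seed = as.integer(seed))
}

#' Parameter-recovery study: planted aging signal vs each model family
#'
#' Simulates the desk-scale recovery cohort, runs the denoising chain,
#' computes static and dynamic FNC, and trains a wide-brain age model of
#' each requested family with grouped 5-fold cross-validation, reporting
#' the cross-validated correlation between predicted and chronological age.
#' Reduced-scale training settings (documented in the methods vignette):
#' ridge at its closed form; graph-convolutional network at 150 epochs;
#' bidirectional LSTM with 24 hidden units, one recurrent layer, 50 epochs,
#' on the top-30 most variable edges of stride-4 window sequences.
#'
#' @param seed Integer seed for cohort generation and training.
#' @param families Model families to run.
#' @return Named list per family: `r` (mean cross-validated correlation),
#'   `mae` (mean cross-validated MAE, years).
#' @export
run_recovery_study <- function(seed,
                               families = c("ridge", "graph_conv", "bilstm")) {
  cfg <- recovery_cohort_config(seed)
  cohort <- simulate_cohort(cfg)
  prepped <- lapply(cohort$timecourses, prep_timecourses)
  ages <- cohort$phenotypes$age
  ids <- cohort$phenotypes$subject_id
  out <- list()
  sfncs <- NULL
  if (any(c("ridge", "graph_conv") %in% families))
    sfncs <- lapply(prepped, static_fnc)
  if ("ridge" %in% families) {
    X <- do.call(rbind, lapply(sfncs, vectorize_fnc))
    fit <- train_predictor(X, ages, model_spec("ridge"),
                           training_config(epochs = 1, folds = 5,
                                           seed = seed),
                           subject_ids = ids)
    out$ridge <- list(r = mean(fit$training$fold_r),
                      mae = mean(fit$training$fold_mae))
  }
  if ("graph_conv" %in% families) {
    fit <- train_predictor(lapply(sfncs, fnc_matrix), ages,
                           model_spec("graph_conv"),
                           training_config(epochs = 150, folds = 5,
                                           seed = seed),
                           subject_ids = ids)
    out$graph_conv <- list(r = mean(fit$training$fold_r),
                           mae = mean(fit$training$fold_mae))
  }
  if ("bilstm" %in% families) {
    dfncs <- lapply(prepped, dynamic_fnc,
                    spec = window_spec(20, 3, stride_tr = 4))
    seqs <- lapply(dfncs, vectorize_dfnc)
    red <- reduce_dfnc_features(seqs, k = 30)
    fit <- train_predictor(red$seqs, ages,
                           model_spec("bilstm", hidden_units = 24,
                                      recurrent_layers = 1, dropout = 0),
                           training_config(epochs = 50, folds = 5,
                                           seed = seed),
                           subject_ids = ids, modality = "dfnc")
    out$bilstm <- list(r = mean(fit$training$fold_r),
                       mae = mean(fit$training$fold_mae))
  }
  out
}

## internal: one simulated clinical sample for GLM studies. BAG is drawn
## independently of the covariates; the outcome couples to BAG through
## generate_cognition() at the requested planted partial correlation.
simulate_glm_sample <- function(n, partial_r, bag_sd = 3, slope = -0.5,
                                n_sites = 3) {
  noise_sd <- if (partial_r == 0) 4
    else abs(slope) * bag_sd * sqrt(1 / partial_r^2 - 1)
  cfg <- cohort_config(n_subjects = n, n_components = 2, n_frames = 2,
                       cognition_slope = if (partial_r == 0) 0 else slope,
                       cognition_noise_sd = noise_sd)
  d <- data.frame(
    subject_id = sprintf("S%04d", seq_len(n)),
    age = stats::runif(n, 40, 60),
    sex = sample(c("F", "M"), n, replace = TRUE),
    site = sample.int(n_sites, n, replace = TRUE),
    diagnosis = as.integer(stats::runif(n) < 0.5),
    bag = stats::rnorm(n, sd = bag_sd))
  cog <- generate_cognition(d$bag, cfg)
  d$attention <- cog$attention
  d$working_memory <- cog$working_memory
  d
}

#' Association-recovery study: planted partial correlation in the GLM
#'
#' Repeatedly simulates a clinical sample with a known partial correlation
#' between BAG and cognition (BAG independent of the covariates; the
#' cognition noise SD is derived in closed form from the target), fits the
#' covariate-adjusted association GLM and records the recovered partial r.
#'
#' @param seed Integer seed.
#' @param n_reps Number of replicates.
#' @param n Sample size per replicate.
#' @param partial_r Planted partial correlation.
#' @return List with `partial_r` (vector over replicates), `mean_r` and
#'   `sign_rate` (fraction of replicates with the planted sign).
#' @export
run_glm_recovery <- function(seed, n_reps = 100, n = 150, partial_r = -0.3) {
  set.seed(seed)
  got <- vapply(seq_len(n_reps), function(i) {
    d <- simulate_glm_sample(n, partial_r)
    fit_association_glm(d, "attention",
                        glm_design(age_filter_min = NULL))$partial_r
  }, numeric(1))
  list(partial_r = got, mean_r = mean(got),
       sign_rate = mean(sign(got) == sign(partial_r)))
}

#' Null-calibration study: FDR family-wise error under no planted signal
#'
#' Repeatedly simulates the two-modality wide-brain family under the global
#' null (cognition independent of BAG) and records how often any test in
#' the family survives FDR correction at alpha = 0.05, plus the raw
#' per-test rejection rate.
#'
#' @param seed Integer seed.
#' @param n_reps Number of replicates.
#' @param n Sample size per replicate.
#' @return List with `family_rate` (fraction of replicates with any
#'   FDR-significant finding), `raw_rate` (per-test raw rejection rate at
#'   0.05) and `n_reps`.
#' @export
run_null_fdr_study <- function(seed, n_reps = 400, n = 150) {
  set.seed(seed)
  any_sig <- logical(n_reps)
  raw <- numeric(0)
  for (i in seq_len(n_reps)) {
    d <- simulate_glm_sample(n, partial_r = 0)
    d2 <- d
    d2$bag <- stats::rnorm(n, sd = 3)   # second modality: independent BAG
    p <- c(fit_association_glm(d, "attention",
                               glm_design(age_filter_min = NULL))$p,
           fit_association_glm(d2, "attention",
                               glm_design(age_filter_min = NULL))$p)
    raw <- c(raw, p)
    any_sig[i] <- any(fdr_correct(p) < 0.05)
  }
  list(family_rate = mean(any_sig), raw_rate = mean(raw < 0.05),
       n_reps = n_reps)
}
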