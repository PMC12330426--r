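#' Pipeline configuration
#'
#' One configuration object for the full simulate - prep - connectivity -
#' train - predict - BAG - associate pipeline. The training cohort is
#' all-control (healthy reference, as brain-age models are fit on healthy
#' subjects); the test cohort shares the same connectivity structure and
#' carries diagnosis and cognition signal.
#'
#' @param cohort A [cohort_config()] describing the test cohort (its
#'   `diagnosis_fraction` applies to the test cohort only).
#' @param n_train Training-cohort size (default: same as the test cohort).
#' @param prep A [prep_config()].
#' @param window A [window_spec()].
#' @param model A [model_spec()].
#' @param training A [training_config()].
#' @param association A [glm_design()]; the default keeps all ages since
#'   synthetic cohorts have no young-age accuracy deficit.
#' @param seed Global seed; propagated to cohort generation and training.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(cohort = cohort_config(),
                            n_train = NULL,
                            prep = prep_config(),
                            window = window_spec(),
                            model = model_spec("ridge"),
                            training = training_config(),
                            association = glm_design(age_filter_min = NULL),
                            seed = 1L) {
  structure(list(cohort = cohort,
                 n_train = if (is.null(n_train)) cohort$n_subjects
                           else as.integer(n_train),
                 prep = prep, window = window, model = model,
                 training = training, association = association,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

## internal: replace fields of a cohort_config
cohort_override <- function(config, ...) {
  args <- list(...)
  for (nm in names(args)) config[[nm]] <- args[[nm]]
  do.call(cohort_config, unclass(config))
}

## internal: digests of every file in a directory (reproducibility record)
dir_digests <- function(dir) {
  files <- sort(list.files(dir, recursive = TRUE, full.names = TRUE))
  d <- tools::md5sum(files)
  names(d) <- sub(paste0("^", dir, "/?"), "", names(d))
  as.list(d)
}

#' Run the full brain-age pipeline
#'
#' Executes, in order: simulate a healthy training cohort and a test cohort
#' sharing its connectivity structure; denoise all scans; compute static and
#' dynamic FNC; train wide-brain age models on the training cohort (the
#' configured family on sFNC features and on window-mean dFNC features);
#' predict test-cohort ages; compute BAGs; and run the covariate-adjusted
#' association suite against attention and working memory. All stage outputs
#' and a run manifest (resolved config, package version, per-stage file
#' digests, timestamps) are written under `out_dir`.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory root.
#' @return Invisibly, a list with `associations` (data frame), `bags`,
#'   `models`, `evaluation` (training-cohort CV metrics) and `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = tempfile("connage_run_")) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  t0 <- Sys.time()

  ## simulate: healthy training cohort + clinical test cohort, shared structure
  train_cfg_cohort <- cohort_override(config$cohort,
                                      n_subjects = config$n_train,
                                      diagnosis_fraction = 0,
                                      seed = config$seed)
  train_cohort <- simulate_cohort(train_cfg_cohort)
  test_cfg_cohort <- cohort_override(config$cohort,
                                     seed = config$seed + 1L)
  test_cohort <- simulate_cohort(test_cfg_cohort,
                                 shared = train_cohort$structure)
  write_cohort(train_cohort, file.path(out_dir, "train_cohort"))
  write_cohort(test_cohort, file.path(out_dir, "test_cohort"))

  ## prep
  prep_train <- lapply(train_cohort$timecourses, prep_timecourses,
                       config = config$prep)
  prep_test <- lapply(test_cohort$timecourses, prep_timecourses,
                      config = config$prep)

  ## connectivity
  sfnc_train <- lapply(prep_train, static_fnc)
  sfnc_test <- lapply(prep_test, static_fnc)
  dfnc_train <- lapply(prep_train, dynamic_fnc, spec = config$window)
  dfnc_test <- lapply(prep_test, dynamic_fnc, spec = config$window)
  X_s_train <- do.call(rbind, lapply(sfnc_train, vectorize_fnc))
  X_s_test <- do.call(rbind, lapply(sfnc_test, vectorize_fnc))
  ## dFNC features for the linear family: window-mean connectivity
  X_d_train <- do.call(rbind, lapply(dfnc_train, function(d)
    colMeans(vectorize_dfnc(d))))
  X_d_test <- do.call(rbind, lapply(dfnc_test, function(d)
    colMeans(vectorize_dfnc(d))))

  ## train wide-brain models (one per modality)
  ages <- train_cohort$phenotypes$age
  tc <- config$training
  tc$seed <- config$seed
  model_s <- train_predictor(X_s_train, ages, config$model, tc,
                             subject_ids = train_cohort$phenotypes$subject_id,
                             scope = "wide", modality = "sfnc")
  model_d <- train_predictor(X_d_train, ages, config$model, tc,
                             subject_ids = train_cohort$phenotypes$subject_id,
                             scope = "wide", modality = "dfnc")

  ## predict + BAG on the test cohort
  pred_s <- data.frame(subject_id = test_cohort$phenotypes$subject_id,
                       predicted_age = predict_age(model_s, X_s_test))
  pred_d <- data.frame(subject_id = test_cohort$phenotypes$subject_id,
                       predicted_age = predict_age(model_d, X_d_test))
  bag_s <- compute_bag(pred_s, test_cohort$phenotypes, "wide", "sfnc")
  bag_d <- compute_bag(pred_d, test_cohort$phenotypes, "wide", "dfnc")
  utils::write.csv(bag_s, file.path(out_dir, "bags_sfnc.csv"),
                   row.names = FALSE)
  utils::write.csv(bag_d, file.path(out_dir, "bags_dfnc.csv"),
                   row.names = FALSE)

  ## associate
  assoc <- run_association_suite(list(bag_s, bag_d),
                                 outcomes = c("attention", "working_memory"),
                                 design = config$association)
  utils::write.csv(assoc, file.path(out_dir, "associations.csv"),
                   row.names = FALSE)

  evaluation <- list(
    sfnc = list(cv_r = mean(model_s$training$fold_r),
                cv_mae = mean(model_s$training$fold_mae)),
    dfnc = list(cv_r = mean(model_d$training$fold_r),
                cv_mae = mean(model_d$training$fold_mae)))

  manifest <- list(
    package_version = as.character(utils::packageVersion("connage")),
    seed = config$seed,
    model_family = config$model$family,
    n_train = config$n_train,
    n_test = config$cohort$n_subjects,
    n_components = config$cohort$n_components,
    window = config$window[c("width_tr", "gaussian_sigma", "stride_tr")],
    started = format(t0, "%Y-%m-%dT%H:%M:%S%z"),
    finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    evaluation = evaluation,
    digests = dir_digests(out_dir))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(associations = assoc, bags = list(sfnc = bag_s, dfnc = bag_d),
                 models = list(sfnc = model_s, dfnc = model_d),
                 evaluation = evaluation, manifest = manifest,
                 out_dir = out_dir))
}
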