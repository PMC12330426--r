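#' Read a component time-course file
#'
#' Reads one delimited (CSV, header row of component ids, UTF-8) time-course
#' file written by [write_timecourses()] or by the cohort writer.
#'
#' @param path CSV path.
#' @param tr_seconds Repetition time of the scan.
#' @param subject_id Subject id; defaults to the file name without
#'   extension.
#' @return A `timecourse_matrix`.
#' @export
read_timecourses <- function(path, tr_seconds,
                             subject_id = tools::file_path_sans_ext(basename(path))) {
  df <- utils::read.csv(path, check.names = FALSE)
  timecourse_matrix(as.matrix(df), tr_seconds, subject_id,
                    component_ids = colnames(df))
}

#' Write a component time-course file
#'
#' @param ts A `timecourse_matrix`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_timecourses <- function(ts, path) {
  assert_timecourse(ts)
  utils::write.csv(as.data.frame(ts$data), path, row.names = FALSE)
  invisible(path)
}

#' Read a phenotype table
#'
#' @param path CSV with at least `subject_id`, `age`, `sex`, `site`,
#'   `diagnosis` (cognition columns optional).
#' @return Data frame of phenotypes.
#' @export
read_phenotypes <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- setdiff(c("subject_id", "age", "sex", "site", "diagnosis"),
                  names(df))
  if (length(need))
    stop("phenotype table missing required columns: ",
         paste(need, collapse = ", "))
  bad <- df$subject_id[!is.finite(df$age)]
  if (length(bad))
    stop("non-finite age for subjects: ", paste(bad, collapse = ", "))
  df
}

#' Write a square connectivity matrix as delimited text
#'
#' @param m Matrix (e.g. an sFNC matrix).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(m, path) {
  utils::write.csv(as.data.frame(m), path, row.names = FALSE)
  invisible(path)
}

#' Write a dynamic-FNC array as a binary container with a JSON sidecar
#'
#' The C x C x T array is stored as little-endian doubles; the sidecar
#' (`<path>.json`) records the subject, dimensions, dimnames and window
#' spec so the array is self-describing.
#'
#' @param dfnc A `dynamic_fnc`.
#' @param path Output path for the binary array (sidecar at `<path>.json`).
#' @return `path`, invisibly.
#' @export
write_dfnc_array <- function(dfnc, path) {
  stopifnot(inherits(dfnc, "dynamic_fnc"))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.vector(dfnc$array), con, size = 8, endian = "little")
  meta <- list(subject_id = dfnc$subject_id, dim = dim(dfnc$array),
               component_ids = dimnames(dfnc$array)[[1]],
               window = dfnc$window[c("width_tr", "gaussian_sigma",
                                      "stride_tr")],
               n_windows = dfnc$n_windows)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a dynamic-FNC array written by [write_dfnc_array()]
#'
#' @param path Path to the binary array (expects `<path>.json` sidecar).
#' @return A `dynamic_fnc`.
#' @export
read_dfnc_array <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  con <- file(path, "rb")
  on.exit(close(con))
  v <- readBin(con, "double", n = prod(meta$dim), size = 8,
               endian = "little")
  arr <- array(v, dim = meta$dim,
               dimnames = list(meta$component_ids, meta$component_ids, NULL))
  spec <- window_spec(meta$window$width_tr, meta$window$gaussian_sigma,
                      meta$window$stride_tr)
  structure(list(array = arr, window = spec, subject_id = meta$subject_id,
                 n_windows = meta$n_windows),
            class = "dynamic_fnc")
}

#' Write a synthetic cohort to disk
#'
#' Writes one time-course CSV per subject (`timecourses/<id>.csv`),
#' `phenotypes.csv`, `truth.csv` (subject_id, effective_age, true_bag) and
#' the resolved generator configuration as `config.yaml`.
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  tcdir <- file.path(dir, "timecourses")
  dir.create(tcdir, recursive = TRUE, showWarnings = FALSE)
  for (ts in cohort$timecourses)
    write_timecourses(ts, file.path(tcdir, paste0(ts$subject_id, ".csv")))
  utils::write.csv(cohort$phenotypes, file.path(dir, "phenotypes.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$truth, file.path(dir, "truth.csv"),
                   row.names = FALSE)
  cfg <- cohort$config
  class(cfg) <- NULL
  yaml::write_yaml(cfg, file.path(dir, "config.yaml"))
  invisible(dir)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param dir Cohort directory.
#' @return List with `timecourses`, `phenotypes`, `truth` and `config`.
#' @export
read_cohort <- function(dir) {
  cfg <- yaml::read_yaml(file.path(dir, "config.yaml"))
  pheno <- read_phenotypes(file.path(dir, "phenotypes.csv"))
  truth_path <- file.path(dir, "truth.csv")
  truth <- if (file.exists(truth_path))
    utils::read.csv(truth_path, stringsAsFactors = FALSE) else NULL
  tcs <- lapply(pheno$subject_id, function(id)
    read_timecourses(file.path(dir, "timecourses", paste0(id, ".csv")),
                     tr_seconds = cfg$tr_seconds, subject_id = id))
  list(timecourses = tcs, phenotypes = pheno, truth = truth, config = cfg)
}
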