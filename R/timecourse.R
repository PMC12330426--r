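#' Construct a component time-course matrix
#'
#' The basic unit consumed and produced by every stage of the pipeline: a
#' frames x components matrix of post-ICA component signals, annotated with
#' the repetition time (TR) of the scan, a subject identifier and ordered
#' component labels.
#'
#' @param data Numeric matrix, frames in rows, components in columns.
#' @param tr_seconds Repetition time in seconds (one frame every `tr_seconds`).
#' @param subject_id Character scalar identifying the scan's subject.
#' @param component_ids Optional character vector of component labels; taken
#'   from `colnames(data)` or generated as `IC1..ICk` when missing.
#'
#' @return An object of class `timecourse_matrix` with fields `data`,
#'   `tr_seconds`, `subject_id` and `component_ids`.
#' @export
timecourse_matrix <- function(data, tr_seconds, subject_id = "subject",
                              component_ids = NULL) {
  data <- as.matrix(data)
  if (!is.numeric(data)) stop("time-course data must be numeric")
  if (!is.numeric(tr_seconds) || length(tr_seconds) != 1L || tr_seconds <= 0)
    stop("tr_seconds must be a single positive number")
  if (is.null(component_ids)) {
    component_ids <- colnames(data)
    if (is.null(component_ids))
      component_ids <- paste0("IC", seq_len(ncol(data)))
  }
  if (length(component_ids) != ncol(data))
    stop("component_ids length must match the number of columns")
  colnames(data) <- component_ids
  structure(
    list(data = data, tr_seconds = as.numeric(tr_seconds),
         subject_id = as.character(subject_id),
         component_ids = as.character(component_ids)),
    class = "timecourse_matrix"
  )
}

#' @export
print.timecourse_matrix <- function(x, ...) {
  cat(sprintf("<timecourse_matrix> subject %s: %d frames x %d components, TR %.3f s (%.1f s)\n",
              x$subject_id, nrow(x$data), ncol(x$data), x$tr_seconds,
              nrow(x$data) * x$tr_seconds))
  invisible(x)
}

#' Number of frames in a time-course matrix
#' @param ts A `timecourse_matrix`.
#' @return Integer frame count.
#' @export
frame_count <- function(ts) {
  stopifnot(inherits(ts, "timecourse_matrix"))
  nrow(ts$data)
}

## internal: replace the data slot, keeping annotations
tc_replace <- function(ts, data) {
  ts$data <- data
  colnames(ts$data) <- ts$component_ids
  ts
}

assert_timecourse <- function(ts) {
  if (!inherits(ts, "timecourse_matrix"))
    stop("expected a 'timecourse_matrix' object")
  if (any(!is.finite(ts$data)))
    stop("time-course data contains non-finite values")
  invisible(ts)
}
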