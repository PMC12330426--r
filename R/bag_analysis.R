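#' Compute brain-age gaps
#'
#' Joins model predictions to phenotypes by subject id and computes the
#' brain-age gap BAG = predicted age - chronological age for every subject.
#'
#' @param predictions Data frame with `subject_id` and `predicted_age`.
#' @param phenotypes Data frame with `subject_id`, `age` and any covariate /
#'   outcome columns (carried through).
#' @param scope Scope label (`"wide"` or a network name).
#' @param modality Modality label (`"sfnc"` or `"dfnc"`).
#' @param bias_correct Apply the standard age-bias correction: predicted
#'   age is regressed on chronological age within a reference group and
#'   predictions are rescaled as `age + (pred - a - b*age)/b`, removing the
#'   regression-to-the-mean shrinkage of the raw predictions. Off by
#'   default.
#' @param reference Logical vector (length `nrow(phenotypes)`) selecting
#'   the reference subjects for the bias fit (e.g. controls); all subjects
#'   when `NULL`.
#' @return A `bag_table` data frame: `subject_id`, `age`, `predicted_age`,
#'   `bag`, `scope`, `modality`, plus the phenotype columns.
#' @export
compute_bag <- function(predictions, phenotypes, scope = "wide",
                        modality = "sfnc", bias_correct = FALSE,
                        reference = NULL) {
  need <- setdiff(c("subject_id", "predicted_age"), names(predictions))
  if (length(need)) stop("predictions missing columns: ",
                         paste(need, collapse = ", "))
  if (!all(c("subject_id", "age") %in% names(phenotypes)))
    stop("phenotypes must contain 'subject_id' and 'age'")
  unmatched <- setdiff(predictions$subject_id, phenotypes$subject_id)
  if (length(unmatched))
    stop("prediction subject ids with no phenotype row: ",
         paste(utils::head(unmatched, 10), collapse = ", "))
  if (anyDuplicated(predictions$subject_id) ||
      anyDuplicated(phenotypes$subject_id))
    stop("subject ids must be unique for a one-to-one join")
  m <- merge(predictions, phenotypes, by = "subject_id", sort = FALSE)
  if (bias_correct) {
    ref <- if (is.null(reference)) rep(TRUE, nrow(phenotypes)) else reference
    refd <- merge(phenotypes[ref, c("subject_id", "age")], predictions,
                  by = "subject_id")
    cf <- stats::coef(stats::lm(predicted_age ~ age, data = refd))
    if (abs(cf[2]) < 1e-8) stop("bias correction undefined: flat prediction")
    m$predicted_age <- m$age + (m$predicted_age - cf[1] - cf[2] * m$age) / cf[2]
  }
  m$bag <- m$predicted_age - m$age
  m$scope <- scope
  m$modality <- modality
  class(m) <- c("bag_table", "data.frame")
  m
}

#' GLM design for BAG-cognition association
#'
#' The covariate-adjusted design used for every association test: the
#' outcome is regressed on the BAG of interest plus age, sex, site
#' (categorical, first site as reference), age squared, the age-by-sex
#' interaction and diagnosis. Age is mean-centered before squaring and
#' interacting (numerical conditioning; the BAG coefficient is unaffected).
#'
#' @param age_filter_min Retain only subjects strictly older than this
#'   (years); `NULL` keeps everyone. The default mirrors restricting a
#'   clinical test sample to ages where the age model is accurate.
#' @param alpha Two-sided significance level for confidence intervals and
#'   FDR flags.
#' @return A `glm_design` list.
#' @export
glm_design <- function(age_filter_min = 38, alpha = 0.05) {
  structure(list(age_filter_min = age_filter_min, alpha = alpha),
            class = "glm_design")
}

#' Test one BAG-outcome association
#'
#' Ordinary least squares of the outcome on
#' `[intercept, bag, age, sex, site, age^2, age x sex, diagnosis]`,
#' reporting the BAG term's beta, SE, t, two-sided p, 95% CI and the
#' partial correlation `r = t / sqrt(t^2 + df)` between BAG and the outcome
#' given the covariates.
#'
#' @param bags A `bag_table` (from [compute_bag()]) whose phenotype columns
#'   include `sex`, `site`, `diagnosis` and the outcome.
#' @param outcome Name of the outcome column.
#' @param design A [glm_design()].
#' @return One-row data frame of class `association_result`: `outcome`,
#'   `scope`, `modality`, `beta`, `se`, `t`, `df`, `p`, `ci_low`, `ci_high`,
#'   `partial_r`, `n`.
#' @export
fit_association_glm <- function(bags, outcome, design = glm_design()) {
  need <- setdiff(c("bag", "age", "sex", "site", "diagnosis", outcome),
                  names(bags))
  if (length(need)) stop("missing columns: ", paste(need, collapse = ", "))
  d <- as.data.frame(bags)
  if (!is.null(design$age_filter_min))
    d <- d[d$age > design$age_filter_min, , drop = FALSE]
  d$site <- factor(d$site)
  d$sex <- factor(d$sex)
  d$age_c <- d$age - mean(d$age)
  fml <- stats::as.formula(paste0(
    "`", outcome, "` ~ bag + age_c + sex + site + I(age_c^2) + ",
    "age_c:sex + diagnosis"))
  X_cols <- 6L + nlevels(d$site) - 1L + (nlevels(d$sex) - 1L) * 2L
  if (nrow(d) <= X_cols + 10L)
    stop("too few subjects after age filter: n = ", nrow(d))
  fit <- stats::lm(fml, data = d)
  if (any(is.na(stats::coef(fit)))) {
    dropped <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("rank-deficient design; dropped columns: ",
         paste(dropped, collapse = ", "))
  }
  sm <- summary(fit)$coefficients
  beta <- sm["bag", "Estimate"]; se <- sm["bag", "Std. Error"]
  tval <- sm["bag", "t value"]; p <- sm["bag", "Pr(>|t|)"]
  df <- fit$df.residual
  tcrit <- stats::qt(1 - design$alpha / 2, df)
  res <- data.frame(outcome = outcome,
                    scope = if ("scope" %in% names(d)) d$scope[1] else NA,
                    modality = if ("modality" %in% names(d)) d$modality[1] else NA,
                    beta = beta, se = se, t = tval, df = df, p = p,
                    ci_low = beta - tcrit * se, ci_high = beta + tcrit * se,
                    partial_r = tval / sqrt(tval^2 + df), n = nrow(d),
                    stringsAsFactors = FALSE)
  class(res) <- c("association_result", "data.frame")
  res
}

#' Benjamini-Hochberg FDR correction
#'
#' Step-up adjusted p-values controlling the false discovery rate within a
#' declared family of tests.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values (same order), each `>=` its raw value.
#' @export
fdr_correct <- function(p_values) {
  if (any(!is.finite(p_values)) || any(p_values < 0) || any(p_values > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Run the full BAG-cognition association suite
#'
#' For each outcome, tests every supplied BAG table against the outcome and
#' applies FDR correction within the declared families: the wide-brain
#' family (one test per modality) and the sub-network family (every
#' network x modality combination — 14 tests with seven networks and two
#' modalities). Raw and adjusted p-values are both reported; significance
#' is flagged at adjusted p below `design$alpha`.
#'
#' @param bag_tables List of `bag_table` objects (each with its `scope` and
#'   `modality` labels).
#' @param outcomes Character vector of outcome column names.
#' @param design A [glm_design()].
#' @return Data frame: one row per outcome x table with all association
#'   fields plus `p_fdr`, `family` and `significant`.
#' @export
run_association_suite <- function(bag_tables,
                                  outcomes = c("attention", "working_memory"),
                                  design = glm_design()) {
  rows <- list()
  for (out in outcomes) {
    for (tab in bag_tables) {
      if (!out %in% names(tab))
        stop("outcome column '", out, "' missing from a BAG table")
      r <- fit_association_glm(tab, out, design)
      r$family <- if (identical(r$scope, "wide")) "wide" else "subnetwork"
      rows[[length(rows) + 1L]] <- r
    }
  }
  res <- do.call(rbind, rows)
  res$p_fdr <- NA_real_
  for (out in unique(res$outcome)) {
    for (fam in unique(res$family)) {
      sel <- res$outcome == out & res$family == fam
      res$p_fdr[sel] <- fdr_correct(res$p[sel])
    }
  }
  res$significant <- res$p_fdr < design$alpha
  rownames(res) <- NULL
  res
}
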