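#' Predictive-stability grid over truncated monitoring windows
#'
#' For each fitted reference course and each window (24, 18, 12, 6 h):
#' apply the window's inclusion filter, recompute every retained
#' patient's EBLUP from the truncated series *against the unchanged
#' course parameters* (fixed effects, G matrix and residual variance are
#' those of the full-data fit; only the per-patient design and SBP
#' vectors change), refit the Step-3 logistic model on the scenario
#' deviations, and report the apparent AUC of its linear predictor.
#'
#' @param cohort An [sbp_cohort()] (unfiltered; each cell applies its own
#'   filter).
#' @param courses A list of fitted `reference_course` objects (one per
#'   degree/outcome of interest), e.g. from [fit_reference_course()] on
#'   full 24 h data.
#' @param windows Subset of `c(24, 18, 12, 6)`.
#' @param use_abs_effects Passed to [fit_outcome_model()].
#' @return data.frame with one row per (outcome, degree, window):
#'   `outcome_name`, `degree`, `window_hours`, `auc`, `n_included`,
#'   `n_excluded`, `flag` (`NA` AUC cells explain themselves here).
#' @export
run_scenarios <- function(cohort, courses, windows = c(24, 18, 12, 6),
                          use_abs_effects = FALSE) {
  stopifnot(inherits(cohort, "sbp_cohort"))
  if (inherits(courses, "reference_course")) courses <- list(courses)
  if (!all(windows %in% c(24, 18, 12, 6)))
    stop_sbp("windows must be a subset of {24, 18, 12, 6}")
  rows <- list()
  for (course in courses) {
    stopifnot(inherits(course, "reference_course"))
    frozen <- list(alpha = course$alpha, G = course$G,
                   sigma2 = course$sigma2)
    for (w in windows) {
      flt <- window_filter(w)
      sel <- apply_inclusion_filter(cohort, flt)
      cell <- tryCatch({
        eff <- eblup_table(sel$included, course, w)
        covs <- cohort_table(sel$included)
        fit <- fit_outcome_model(eff, covs, course$spec$outcome_name,
                                 use_abs_effects)
        list(auc = compute_auc(fit$scores, fit$labels), n = fit$n_used,
             flag = NA_character_)
      }, error = function(e)
        list(auc = NA_real_, n = length(sel$included),
             flag = conditionMessage(e)))
      # the course must come out of the cell exactly as it went in
      stopifnot(identical(frozen$alpha, course$alpha),
                identical(frozen$G, course$G),
                identical(frozen$sigma2, course$sigma2))
      rows[[length(rows) + 1L]] <- data.frame(
        outcome_name = course$spec$outcome_name,
        degree = course$spec$degree, window_hours = w,
        auc = cell$auc, n_included = cell$n,
        n_excluded = sel$n_excluded, flag = cell$flag,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
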