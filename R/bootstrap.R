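#' Full-pipeline bootstrap confidence intervals
#'
#' The three-step pipeline treats the Step-1 course and the Step-2
#' deviations as known when fitting Step 3, which understates the
#' uncertainty of the final coefficients. The bootstrap reruns *all*
#' steps on each resample: patients are resampled with replacement from
#' the (already inclusion-filtered) cohort, the favourable subgroup is
#' re-identified within the resample, the reference course refit, EBLUPs
#' recomputed, and the logistic model refit. Percentile 2.5 / 97.5
#' quantiles of the resampled coefficients give the 95% CIs.
#'
#' Iteration-level fit failures (e.g. non-convergence on a degenerate
#' resample) are recorded and skipped; the run is flagged when 10% or
#' more iterations fail. Per-iteration RNG substreams are derived from
#' `seed`, so results are reproducible and independent of failure
#' patterns.
#'
#' @param cohort An [sbp_cohort()] that already passed the 24 h inclusion
#'   filter.
#' @param spec A [course_spec()].
#' @param n_iterations Bootstrap iterations (default 1000).
#' @param seed Master seed.
#' @param fit_config Passed to [fit_reference_course()].
#' @param use_abs_effects Passed to [fit_outcome_model()].
#' @param .identity Internal: if `TRUE`, every "resample" is the identity
#'   (used to verify that the bootstrap machinery reproduces the point
#'   estimates exactly).
#' @return A `bootstrap_result`: the point-estimate `fit`
#'   (an `outcome_model_fit` with CI columns filled in), `ci` table,
#'   `n_iterations`, `n_failed_iterations`, `flagged`, `seed`, and the
#'   matrix of resampled coefficients.
#' @export
bootstrap_pipeline <- function(cohort, spec, n_iterations = 1000, seed = 1L,
                               fit_config = list(),
                               use_abs_effects = FALSE,
                               .identity = FALSE) {
  stopifnot(inherits(cohort, "sbp_cohort"), inherits(spec, "course_spec"))
  point <- pipeline_once(cohort, spec, fit_config, use_abs_effects)
  terms <- point$fit$coefficients$term
  draws <- matrix(NA_real_, n_iterations, length(terms),
                  dimnames = list(NULL, terms))
  n <- length(cohort)
  records <- unclass(cohort)
  n_failed <- 0L
  for (it in seq_len(n_iterations)) {
    set.seed(derive_seed(seed, it, stream = 2L))
    idx <- if (.identity) seq_len(n) else sample.int(n, n, replace = TRUE)
    res <- lapply(seq_along(idx), function(k) {
      r <- records[[idx[k]]]
      r$patient_id <- sprintf("%s.b%d", r$patient_id, k)  # unique ids
      r
    })
    ans <- tryCatch(
      pipeline_once(sbp_cohort(res), spec, fit_config, use_abs_effects),
      error = function(e) NULL)
    if (is.null(ans)) { n_failed <- n_failed + 1L; next }
    b <- ans$fit$coefficients
    draws[it, b$term] <- b$estimate
  }
  ok <- stats::complete.cases(draws)
  ci <- t(apply(draws[ok, , drop = FALSE], 2, quantile,
                probs = c(0.025, 0.975), names = FALSE))
  fit <- point$fit
  m <- match(fit$coefficients$term, rownames(ci))
  fit$coefficients$ci_lower <- ci[m, 1]
  fit$coefficients$ci_upper <- ci[m, 2]
  flagged <- n_failed >= 0.1 * n_iterations
  if (flagged)
    warn_sbp("%d of %d bootstrap iterations failed (>= 10%%)", n_failed,
             n_iterations)
  structure(list(fit = fit, course = point$course,
                 ci = data.frame(term = rownames(ci), ci_lower = ci[, 1],
                                 ci_upper = ci[, 2], row.names = NULL),
                 n_iterations = n_iterations,
                 n_failed_iterations = n_failed, flagged = flagged,
                 seed = seed, draws = draws),
            class = "bootstrap_result")
}

# One pass of Steps 1-3 on a cohort: course on favourable subgroup,
# EBLUPs for everyone, logistic outcome model.
pipeline_once <- function(cohort, spec, fit_config = list(),
                          use_abs_effects = FALSE, window_hours = 24) {
  fav <- favourable_subcohort(cohort, spec$outcome_name)
  fc <- modifyList(list(check_outcome = FALSE), fit_config)
  course <- fit_reference_course(fav, spec, fc)
  eff <- eblup_table(cohort, course, window_hours)
  covs <- cohort_table(cohort)
  fit <- fit_outcome_model(eff, covs, spec$outcome_name, use_abs_effects)
  list(course = course, effects = eff, fit = fit)
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf(
    "Bootstrap of the full pipeline: %d iterations (%d failed)%s\n",
    x$n_iterations, x$n_failed_iterations,
    if (x$flagged) " [FLAGGED]" else ""))
  print(x$fit$coefficients, digits = 3, row.names = FALSE)
  invisible(x)
}
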