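#' Logistic outcome model on EBLUP deviations and clinical covariates
#'
#' Fits the Step-3 model: the binary outcome against all random-effect
#' deviation components simultaneously, plus age, sex, baseline NIHSS,
#' hypertension history and recanalisation success (mTICI 2b-3). Cases
#' with a missing outcome or covariate are dropped (listwise deletion).
#'
#' @param effects_table data.frame from [eblup_table()].
#' @param covariates data.frame with `patient_id`, `age`, `sex`,
#'   `nihss_baseline`, `hypertension`, `mtici_success` and the outcome
#'   column (e.g. from [cohort_table()]).
#' @param outcome_name Name of the binary outcome column in `covariates`.
#' @param use_abs_effects If `TRUE`, enter absolute deviations |effect|
#'   instead of signed deviations (a magnitude-of-deviation predictor).
#'   Default `FALSE` (signed).
#' @return An `outcome_model_fit`: coefficient table (log-odds, odds
#'   ratios, CI slots filled by [bootstrap_pipeline()]), `n_used`, the
#'   underlying `glm` object, and the score (linear predictor) per used
#'   patient.
#' @export
fit_outcome_model <- function(effects_table, covariates, outcome_name,
                              use_abs_effects = FALSE) {
  outcome_name <- match.arg(outcome_name, outcome_names())
  eff_cols <- effect_columns(effects_table)
  if (!length(eff_cols)) stop_sbp("effects_table has no effect_* columns")
  cov_cols <- c("age", "sex", "nihss_baseline", "hypertension",
                "mtici_success")
  missing_cols <- setdiff(c("patient_id", cov_cols, outcome_name),
                          names(covariates))
  if (length(missing_cols))
    stop_sbp("covariates table lacks column(s): %s",
             paste(missing_cols, collapse = ", "))
  df <- merge(effects_table[, c("patient_id", eff_cols)],
              covariates[, c("patient_id", cov_cols, outcome_name)],
              by = "patient_id")
  if (use_abs_effects) df[eff_cols] <- lapply(df[eff_cols], abs)
  df <- df[complete.cases(df), , drop = FALSE]
  y <- df[[outcome_name]]
  if (sum(y == 1) < 10 || sum(y == 0) < 10)
    stop_sbp("need at least 10 events and 10 non-events (have %d / %d)",
             sum(y == 1), sum(y == 0))
  predictors <- c(eff_cols, cov_cols)
  fml <- stats::reformulate(predictors, response = outcome_name)
  fit <- suppressWarnings(glm(fml, data = df, family = binomial()))
  if (fit$deviance < 1e-6) {
    sep <- detect_separating_column(df[predictors], y)
    stop_sbp("perfect separation detected%s",
             if (is.na(sep)) "" else sprintf(" (column '%s')", sep))
  }
  beta <- coef(fit)
  tab <- data.frame(term = names(beta), estimate = unname(beta),
                    odds_ratio = exp(unname(beta)),
                    ci_lower = NA_real_, ci_upper = NA_real_,
                    stringsAsFactors = FALSE)
  structure(list(outcome_name = outcome_name, coefficients = tab,
                 n_used = nrow(df), effect_columns = eff_cols,
                 use_abs_effects = use_abs_effects, glm = fit,
                 scores = setNames(fit$linear.predictors, df$patient_id),
                 labels = setNames(y, df$patient_id)),
            class = "outcome_model_fit")
}

# A single column whose class-conditional ranges do not overlap separates
# the data on its own; reported to make separation failures actionable.
detect_separating_column <- function(X, y) {
  for (nm in names(X)) {
    x <- X[[nm]]
    if (max(x[y == 1]) < min(x[y == 0]) || max(x[y == 0]) < min(x[y == 1]))
      return(nm)
  }
  NA_character_
}

#' Score new patients with a fitted outcome model
#' @param fit An `outcome_model_fit`.
#' @param effects_table,covariates As in [fit_outcome_model()].
#' @return Named vector of linear-predictor scores (monotone in the
#'   predicted probability, hence AUC-equivalent).
#' @export
score_patients <- function(fit, effects_table, covariates) {
  stopifnot(inherits(fit, "outcome_model_fit"))
  cov_cols <- c("age", "sex", "nihss_baseline", "hypertension",
                "mtici_success")
  df <- merge(effects_table[, c("patient_id", fit$effect_columns)],
              covariates[, c("patient_id", cov_cols)], by = "patient_id")
  if (fit$use_abs_effects)
    df[fit$effect_columns] <- lapply(df[fit$effect_columns], abs)
  df <- df[complete.cases(df), , drop = FALSE]
  setNames(drop(stats::predict(fit$glm, newdata = df, type = "link")),
           df$patient_id)
}

#' @export
print.outcome_model_fit <- function(x, ...) {
  cat(sprintf("Logistic outcome model: %s (n = %d)\n", x$outcome_name,
              x$n_used))
  print(x$coefficients, digits = 3, row.names = FALSE)
  invisible(x)
}

#' Area under the ROC curve (Mann-Whitney form)
#'
#' The probability that a randomly chosen event outranks a randomly
#' chosen non-event, counting ties as 1/2 — computed from midranks, which
#' is exactly the pairwise definition.
#'
#' @param scores Numeric scores (higher = more event-like).
#' @param labels Binary labels (0/1), both classes present.
#' @return AUC in \[0, 1\].
#' @export
compute_auc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  keep <- !is.na(scores) & !is.na(labels)
  scores <- scores[keep]; labels <- labels[keep]
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0)
    stop_sbp("both classes must be present to compute an AUC")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Favourable-outcome proportion of a cohort
#'
#' Headline percentage: favourable count over the full registered
#' denominator (patients with a missing label count in the denominator,
#' not the numerator), rounded to one decimal.
#'
#' @param cohort An [sbp_cohort()] (non-empty).
#' @param outcome_name Outcome label name.
#' @return Percentage, one decimal.
#' @export
cohort_proportions <- function(cohort, outcome_name) {
  stopifnot(inherits(cohort, "sbp_cohort"))
  if (!length(cohort)) stop_sbp("cohort is empty")
  outcome_name <- match.arg(outcome_name, outcome_names())
  lab <- vapply(cohort, function(p) {
    v <- p$outcomes[[outcome_name]]
    if (is.null(v)) NA_integer_ else as.integer(v)
  }, integer(1))
  round(100 * sum(lab == 1, na.rm = TRUE) / length(lab), 1)
}

#' Favourable subcohort for a given outcome
#' @param cohort An [sbp_cohort()].
#' @param outcome_name Outcome label name.
#' @return The patients with label 1 (missing labels excluded).
#' @export
favourable_subcohort <- function(cohort, outcome_name) {
  stopifnot(inherits(cohort, "sbp_cohort"))
  outcome_name <- match.arg(outcome_name, outcome_names())
  keep <- vapply(cohort, function(p)
    isTRUE(p$outcomes[[outcome_name]] == 1L), logical(1))
  sbp_cohort(unclass(cohort)[keep])
}
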