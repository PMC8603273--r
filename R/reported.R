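#' Reported reference-course fixed effects (worked-example inputs)
#'
#' Fixed-effect estimates of the reference SBP course reported for a
#' single-centre thrombectomy cohort of 374 patients, by favourable
#' outcome and polynomial degree. These are *inputs* for worked examples
#' (e.g. evaluating the linear functional-independence course at 0 and
#' 24 h), not quantities this package re-estimates: the underlying
#' hospital data are not publicly deposited.
#'
#' @return data.frame with columns `outcome_name`, `degree`, `level`
#'   (mm Hg), `trend` (mm Hg/h), `curvature` (mm Hg/h^2), `twist`
#'   (mm Hg/h^3); curvature/twist are `NA` where the degree does not use
#'   them.
#' @seealso [reported_course()], [reported_cohort_counts()]
#' @export
reported_fixed_effects <- function() {
  data.frame(
    outcome_name = rep(c("functional_independence", "alive", "no_sich",
                         "no_ich"), each = 3),
    degree = rep(1:3, times = 4),
    level = c(129.78, 132.50, 133.54,
              131.02, 133.34, 134.06,
              131.99, 134.06, 134.57,
              132.22, 134.27, 134.93),
    trend = c(-0.28378, -1.2406, -1.9443,
              -0.23423, -1.0488, -1.5385,
              -0.21927, -0.94195, -1.2899,
              -0.22255, -0.93689, -1.3832),
    curvature = c(NA, 0.04379, 0.12573,
                  NA, 0.03721, 0.09416,
                  NA, 0.03302, 0.07348,
                  NA, 0.03259, 0.08448),
    twist = c(NA, NA, -0.00240,
              NA, NA, -0.00166,
              NA, NA, -0.00118,
              NA, NA, -0.00151),
    stringsAsFactors = FALSE)
}

#' Reference course built from the reported fixed effects
#'
#' Fixed-effects-only course (no G matrix or residual variance, which
#' were not reported to full precision), suitable for
#' [evaluate_course()] worked examples.
#'
#' @param outcome_name Outcome label.
#' @param degree 1, 2 or 3.
#' @return A `reference_course`.
#' @examples
#' rc <- reported_course("functional_independence", 1)
#' round(evaluate_course(rc, c(0, 24))) # 130 and 123 mm Hg
#' @export
reported_course <- function(outcome_name = "functional_independence",
                            degree = 1) {
  tab <- reported_fixed_effects()
  row <- tab[tab$outcome_name == outcome_name & tab$degree == degree, ]
  if (nrow(row) != 1) stop_sbp("no reported course for %s degree %s",
                               outcome_name, degree)
  alpha <- as.numeric(row[c("level", "trend", "curvature",
                            "twist")])[seq_len(degree + 1)]
  reference_course(course_spec(degree, outcome_name), alpha = alpha,
                   n_patients_fit = 374L)
}

#' Reported cohort counts (worked-example inputs)
#'
#' Registered cohort size and favourable-outcome counts reported for the
#' same 374-patient cohort, plus the number excluded for having fewer
#' than 10 SBP measurements in the first 24 h.
#'
#' @return Named list of integer counts.
#' @export
reported_cohort_counts <- function() {
  list(n_registered = 374L,
       functional_independence = 169L,
       alive = 292L,
       no_sich = 354L,
       no_ich = 321L,
       excluded_lt10_measurements = 58L)
}
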