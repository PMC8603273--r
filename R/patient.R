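#' Patient record and cohort containers
#'
#' A `patient_record` holds one patient's irregular SBP series (hours since
#' end of EVT, mm Hg) together with baseline covariates and binary outcome
#' labels. A `sbp_cohort` is a list of records with unique patient ids.
#'
#' @param patient_id Scalar identifier (coerced to character).
#' @param times Numeric vector of measurement times in hours, strictly
#'   increasing, all within \[0, 24\].
#' @param sbp Numeric vector of SBP values (mm Hg), same length as `times`,
#'   strictly positive.
#' @param age Age in years.
#' @param sex 1 = male, 0 = female.
#' @param nihss_baseline Baseline NIHSS score (0-42).
#' @param hypertension History of hypertension (0/1).
#' @param mtici_success Successful recanalisation, mTICI 2b-3 (0/1).
#' @param outcomes Named list or vector with entries
#'   `functional_independence`, `alive`, `no_sich`, `no_ich`; each 0, 1 or
#'   `NA` (missing label).
#' @return An object of class `patient_record`.
#' @export
patient_record <- function(patient_id, times, sbp,
                           age = NA_real_, sex = NA_integer_,
                           nihss_baseline = NA_integer_,
                           hypertension = NA_integer_,
                           mtici_success = NA_integer_,
                           outcomes = list()) {
  out <- setNames(rep(NA_integer_, length(outcome_names())), outcome_names())
  if (length(outcomes)) {
    bad <- setdiff(names(outcomes), outcome_names())
    if (length(bad)) stop_sbp("unknown outcome name(s): %s",
                              paste(bad, collapse = ", "))
    out[names(outcomes)] <- as.integer(unlist(outcomes))
  }
  rec <- structure(list(
    patient_id = as.character(patient_id)[1],
    times = as.numeric(times),
    sbp = as.numeric(sbp),
    age = as.numeric(age),
    sex = as.integer(sex),
    nihss_baseline = as.integer(nihss_baseline),
    hypertension = as.integer(hypertension),
    mtici_success = as.integer(mtici_success),
    outcomes = as.list(out)
  ), class = "patient_record")
  validate_patient_record(rec)
  rec
}

outcome_names <- function() {
  c("functional_independence", "alive", "no_sich", "no_ich")
}

validate_patient_record <- function(rec) {
  if (length(rec$times) != length(rec$sbp))
    stop_sbp("patient %s: times and sbp differ in length", rec$patient_id)
  if (length(rec$times)) {
    if (any(rec$times < 0 | rec$times > 24))
      stop_sbp("patient %s: measurement times must lie in [0, 24] hours",
               rec$patient_id)
    if (is.unsorted(rec$times, strictly = TRUE))
      stop_sbp("patient %s: times must be strictly increasing",
               rec$patient_id)
    if (any(rec$sbp <= 0))
      stop_sbp("patient %s: SBP values must be positive", rec$patient_id)
  }
  ok <- vapply(rec$outcomes, function(v) is.na(v) || v %in% c(0L, 1L),
               logical(1))
  if (!all(ok))
    stop_sbp("patient %s: outcome labels must be 0, 1 or NA", rec$patient_id)
  invisible(rec)
}

#' @rdname patient_record
#' @param records List of `patient_record` objects.
#' @export
sbp_cohort <- function(records) {
  stopifnot(is.list(records))
  for (r in records) {
    if (!inherits(r, "patient_record"))
      stop_sbp("all cohort elements must be patient_record objects")
  }
  ids <- vapply(records, `[[`, character(1), "patient_id")
  if (anyDuplicated(ids))
    stop_sbp("duplicate patient ids in cohort: %s",
             paste(unique(ids[duplicated(ids)]), collapse = ", "))
  structure(records, names = ids, class = "sbp_cohort")
}

#' @export
print.patient_record <- function(x, ...) {
  cat(sprintf("Patient %s: %d SBP measurements over [%s, %s] h\n",
              x$patient_id, length(x$times),
              if (length(x$times)) min(x$times) else "-",
              if (length(x$times)) max(x$times) else "-"))
  invisible(x)
}

#' @export
print.sbp_cohort <- function(x, ...) {
  nm <- vapply(x, function(r) length(r$times), integer(1))
  cat(sprintf("SBP cohort: %d patients, median %s measurements each\n",
              length(x), if (length(x)) stats::median(nm) else "-"))
  invisible(x)
}

#' @export
`[.sbp_cohort` <- function(x, i) {
  sbp_cohort(unclass(x)[i])
}

# Covariate data.frame view of a cohort (one row per patient).
#' Per-patient covariate and outcome table
#' @param cohort An `sbp_cohort`.
#' @return data.frame with one row per patient: id, covariates, outcome
#'   labels and the in-cohort measurement count.
#' @export
cohort_table <- function(cohort) {
  stopifnot(inherits(cohort, "sbp_cohort"))
  recs <- unclass(cohort)
  num <- function(f) vapply(recs, function(r) as.numeric(r[[f]]), numeric(1))
  int <- function(f) vapply(recs, function(r) as.integer(r[[f]]), integer(1))
  out_lab <- function(nm) vapply(recs, function(r)
    as.integer(r$outcomes[[nm]]), integer(1))
  data.frame(patient_id = vapply(recs, `[[`, character(1), "patient_id"),
             age = num("age"), sex = int("sex"),
             nihss_baseline = int("nihss_baseline"),
             hypertension = int("hypertension"),
             mtici_success = int("mtici_success"),
             functional_independence = out_lab("functional_independence"),
             alive = out_lab("alive"), no_sich = out_lab("no_sich"),
             no_ich = out_lab("no_ich"),
             n_measurements = vapply(recs, function(r)
               length(r$times), integer(1)),
             stringsAsFactors = FALSE, row.names = NULL)
}
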