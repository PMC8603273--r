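#' Read a cohort from the two-file CSV layout
#'
#' The long-format SBP file has columns `patient_id, time_h, sbp_mmhg`
#' (decimal hours, "." decimal separator); the covariate file has
#' `patient_id, age, sex, nihss_baseline, hypertension, mtici_success`
#' plus one column per outcome label, with empty cells read as missing.
#' Validation failures report data line numbers (header = line 1).
#'
#' @param sbp_path Path to the long-format SBP CSV.
#' @param covariate_path Path to the per-patient covariate/outcome CSV.
#' @return An [sbp_cohort()]. Patients present in the SBP file but absent
#'   from the covariate file are dropped with a warning; duplicate
#'   `(patient_id, time_h)` rows and SBP outside \[30, 300\] mm Hg are
#'   errors.
#' @export
read_cohort <- function(sbp_path, covariate_path) {
  sbp <- read.csv(sbp_path, stringsAsFactors = FALSE)
  need <- c("patient_id", "time_h", "sbp_mmhg")
  if (!all(need %in% names(sbp)))
    stop_sbp("SBP file must have columns %s", paste(need, collapse = ", "))
  sbp$patient_id <- as.character(sbp$patient_id)
  line <- seq_len(nrow(sbp)) + 1L  # header is line 1
  dup <- duplicated(sbp[c("patient_id", "time_h")])
  if (any(dup))
    stop_sbp("duplicate (patient_id, time_h) at line(s) %s of %s",
             paste(line[dup], collapse = ", "), sbp_path)
  bad <- which(!is.finite(sbp$sbp_mmhg) | sbp$sbp_mmhg < 30 |
                 sbp$sbp_mmhg > 300)
  if (length(bad))
    stop_sbp("SBP outside [30, 300] mm Hg at line(s) %s of %s",
             paste(line[bad], collapse = ", "), sbp_path)
  bad_t <- which(!is.finite(sbp$time_h) | sbp$time_h < 0 | sbp$time_h > 24)
  if (length(bad_t))
    stop_sbp("time_h outside [0, 24] at line(s) %s of %s",
             paste(line[bad_t], collapse = ", "), sbp_path)

  cov <- read.csv(covariate_path, stringsAsFactors = FALSE)
  need_cov <- c("patient_id", "age", "sex", "nihss_baseline",
                "hypertension", "mtici_success")
  if (!all(need_cov %in% names(cov)))
    stop_sbp("covariate file must have columns %s",
             paste(need_cov, collapse = ", "))
  cov$patient_id <- as.character(cov$patient_id)
  if (anyDuplicated(cov$patient_id))
    stop_sbp("duplicate patient_id in %s", covariate_path)

  orphan <- setdiff(unique(sbp$patient_id), cov$patient_id)
  if (length(orphan))
    warn_sbp("%d patient(s) in SBP file missing from covariate file; excluded: %s",
             length(orphan), paste(head(orphan, 5), collapse = ", "))

  records <- lapply(seq_len(nrow(cov)), function(i) {
    id <- cov$patient_id[i]
    rows <- sbp[sbp$patient_id == id, , drop = FALSE]
    ord <- order(rows$time_h)
    outc <- lapply(intersect(outcome_names(), names(cov)), function(nm) {
      v <- cov[[nm]][i]
      if (is.na(v) || v == "") NA_integer_ else as.integer(v)
    })
    names(outc) <- intersect(outcome_names(), names(cov))
    patient_record(id, rows$time_h[ord], rows$sbp_mmhg[ord],
                   age = cov$age[i], sex = cov$sex[i],
                   nihss_baseline = cov$nihss_baseline[i],
                   hypertension = cov$hypertension[i],
                   mtici_success = cov$mtici_success[i],
                   outcomes = outc)
  })
  sbp_cohort(records)
}

#' Write a cohort to the two-file CSV layout
#' @param cohort An [sbp_cohort()].
#' @param sbp_path,covariate_path Output paths.
#' @return Invisibly, the two paths.
#' @export
write_cohort <- function(cohort, sbp_path, covariate_path) {
  stopifnot(inherits(cohort, "sbp_cohort"))
  long <- do.call(rbind, lapply(cohort, function(p) {
    if (!length(p$times)) return(NULL)
    data.frame(patient_id = p$patient_id, time_h = p$times,
               sbp_mmhg = p$sbp, stringsAsFactors = FALSE)
  }))
  write.csv(long, sbp_path, row.names = FALSE, quote = FALSE)
  write.csv(cohort_table(cohort)[, -which(
    names(cohort_table(cohort)) == "n_measurements")],
    covariate_path, row.names = FALSE, quote = FALSE)
  invisible(c(sbp_path, covariate_path))
}
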