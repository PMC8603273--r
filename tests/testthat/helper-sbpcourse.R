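# Shared fixtures, built in code once per test run.

# Moderate cohort reused across test files (favourable subgroup ~ half).
shared_cohort <- generate_cohort(synthetic_config(n_patients = 120, seed = 42))
shared_included <- apply_inclusion_filter(shared_cohort, window_filter(24))$included
shared_fav <- favourable_subcohort(shared_included, "functional_independence")
shared_course <- suppressWarnings(
  fit_reference_course(shared_fav, course_spec(1)))

# Patient whose SBP lies exactly on a given course (zero residual).
exact_patient <- function(course, times = c(0, 6, 12, 24), id = "X1") {
  mu <- drop(polynomial_design(times, course$spec$degree) %*% course$alpha)
  patient_record(id, times, mu, age = 70, sex = 1, nihss_baseline = 12,
                 hypertension = 0, mtici_success = 1,
                 outcomes = list(functional_independence = 1L))
}

# Deterministic cohort with prescribed measurement counts and labels;
# SBP values follow a fixed line plus small deterministic wiggle.
counted_cohort <- function(n_counts, labels = NULL) {
  sched <- default_schedule()
  records <- lapply(seq_along(n_counts), function(i) {
    k <- n_counts[i]
    times <- sched$scheduled[seq_len(k)]
    sbp <- 130 - 0.3 * times + sin(i + times)
    outc <- if (is.null(labels)) list() else
      list(functional_independence = labels[i])
    patient_record(sprintf("C%03d", i), times, sbp, age = 70, sex = 1,
                   nihss_baseline = 10, hypertension = 0,
                   mtici_success = 1, outcomes = outc)
  })
  sbp_cohort(records)
}
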