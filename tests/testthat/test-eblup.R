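test_that("window truncation keeps exactly the in-window measurements", {
  p <- patient_record("W1", c(0, 2, 5, 9, 13, 20), 120 + 1:6)
  expect_identical(truncate_window(p, 24), p)
  tr <- truncate_window(p, 12)
  expect_equal(tr$times, c(0, 2, 5, 9))
  expect_equal(tr$sbp, 120 + 1:4)
  # boundary is inclusive
  pb <- patient_record("W2", c(0, 6, 10), c(120, 121, 122))
  expect_equal(truncate_window(pb, 6)$times, c(0, 6))
  # degenerate: everything after the window
  pe <- patient_record("W3", c(7, 9), c(120, 121))
  expect_length(truncate_window(pe, 6)$times, 0)
  expect_error(truncate_window(p, 20), "24, 18, 12, 6")
})

test_that("window filters carry the stated minimum-measurement map", {
  mins <- vapply(c(24, 18, 12, 6),
                 function(w) window_filter(w)$min_measurements, integer(1))
  expect_equal(mins, c(10L, 8L, 6L, 3L))
})

test_that("inclusion filter reproduces the 374 -> 316 worked example", {
  # 58 of 374 patients below 10 measurements in 24 h
  counts <- c(rep(21L, 316), rep(9L, 58))
  cohort <- counted_cohort(counts)
  res <- apply_inclusion_filter(cohort, window_filter(24))
  expect_length(res$included, 316)
  expect_equal(res$n_excluded, 58L)
  # the protocol guarantees >= 3 measurements in 0-6 h: nobody excluded
  res6 <- apply_inclusion_filter(counted_cohort(rep(21L, 20)),
                                 window_filter(6))
  expect_length(res6$included, 20)
  expect_equal(res6$n_excluded, 0L)
  # empty cohort passes through
  empty <- apply_inclusion_filter(sbp_cohort(list()), window_filter(24))
  expect_length(empty$included, 0)
  expect_equal(empty$n_excluded, 0L)
})

test_that("zero residual implies zero deviation", {
  p <- exact_patient(shared_course)
  eff <- compute_eblup(p, shared_course)$effects
  expect_lt(max(abs(eff)), 1e-10)
})

test_that("single measurement at t = 0 matches the scalar closed form", {
  g0 <- 80; g1 <- 0.3; s2 <- 50; a <- 128; q <- 141
  rc <- reference_course(course_spec(1), alpha = c(a, -0.3),
                         G = diag(c(g0, g1)), sigma2 = s2)
  p <- patient_record("S1", 0, q)
  eff <- compute_eblup(p, rc)$effects
  expect_equal(unname(eff), c(g0 * (q - a) / (g0 + s2), 0),
               tolerance = 1e-12)
})

test_that("EBLUP equals the dense MVN conditional mean", {
  for (p in unclass(shared_included)[1:25]) {
    fast <- compute_eblup(p, shared_course)$effects
    dense <- mvn_conditional_oracle(p, shared_course)
    expect_lt(max(abs(fast - dense)), 1e-6)
  }
})

test_that("shrinkage limits behave as the formula dictates", {
  p <- shared_included[[3]]
  big <- shared_course; big$sigma2 <- shared_course$sigma2 * 1e6
  eff_big <- compute_eblup(p, big)$effects
  expect_lt(max(abs(eff_big)), 1e-2)   # towards the population course

  small <- shared_course; small$sigma2 <- shared_course$sigma2 * 1e-6
  eff_small <- compute_eblup(p, small)$effects
  Z <- polynomial_design(p$times, 1)
  r <- p$sbp - drop(Z %*% shared_course$alpha)
  ls_fit <- drop(Z %*% qr.solve(Z, r))   # per-patient least squares
  expect_lt(max(abs(drop(Z %*% eff_small) - ls_fit)), 1e-3)
})

test_that("conditional variance shrinks as the window grows", {
  p <- shared_included[[2]]
  vars <- sapply(c(6, 12, 18, 24), function(w)
    diag(mvn_conditional_variance(p, shared_course, w)))
  # each component's uncertainty is non-increasing in information
  expect_true(all(diff(t(vars))[, 1] <= 1e-12))
  expect_true(all(diff(t(vars))[, 2] <= 1e-12))
})

test_that("favourable and unfavourable patients share one EBLUP path", {
  eff <- eblup_table(shared_included, shared_course, 24)
  expect_equal(nrow(eff), length(shared_included))
  labs <- cohort_table(shared_included)$functional_independence
  expect_true(any(labs == 0, na.rm = TRUE) && any(labs == 1, na.rm = TRUE))
  expect_true(all(is.finite(as.matrix(eff[grep("^effect_", names(eff))]))))
})

test_that("EBLUP refuses patients with no in-window data", {
  pe <- patient_record("E1", c(10, 14), c(130, 131), age = 60, sex = 0,
                       nihss_baseline = 9, hypertension = 0,
                       mtici_success = 1)
  expect_error(compute_eblup(pe, shared_course, 6), "no measurements")
})
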