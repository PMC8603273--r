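test_that("polynomial design matrices are exact powers", {
  expect_equal(polynomial_design(0, 1), matrix(c(1, 0), 1))
  expect_equal(polynomial_design(2, 3), matrix(c(1, 2, 4, 8), 1))
  expect_equal(polynomial_design(c(0, 24), 2),
               rbind(c(1, 0, 0), c(1, 24, 576)))
  expect_error(polynomial_design(numeric(0), 1), "non-empty")
  expect_error(polynomial_design(c(0, 25), 1), "\\[0, 24\\]")
  expect_error(polynomial_design(1, 4), "degree")
})

test_that("course evaluation reproduces the reported worked example", {
  rc <- reported_course("functional_independence", 1)
  expect_equal(round(evaluate_course(rc, 24)), 123)
  expect_equal(evaluate_course(rc, 0), 129.78)
  zero <- reference_course(course_spec(1), alpha = c(0, 0))
  expect_equal(evaluate_course(zero, c(0, 7, 24)), c(0, 0, 0))
  expect_error(evaluate_course(rc, 25), "\\[0, 24\\]")
})

test_that("noiseless data recovers the generating line essentially exactly", {
  # 20 patients whose SBP lies exactly on 120 - 0.5 t: the G = 0,
  # sigma2 -> 0 degenerate limit of the model
  times <- default_schedule()$scheduled
  recs <- lapply(1:20, function(i)
    patient_record(paste0("N", i), times, 120 - 0.5 * times))
  fit <- suppressWarnings(
    fit_reference_course(sbp_cohort(recs), course_spec(1),
                         fit_config = list(check_outcome = FALSE)))
  expect_lt(max(abs(fit$alpha - c(120, -0.5))), 1e-4)
})

test_that("parameters are recovered on a simulated cohort (n = 300)", {
  cfg <- synthetic_config(n_patients = 300, true_alpha = c(130, -0.28),
                          true_G = diag(c(100, 0.25)), true_sigma2 = 64,
                          force_below_min_frac = 0, seed = 301)
  cohort <- generate_cohort(cfg)
  fit <- fit_reference_course(cohort, course_spec(1),
                              fit_config = list(check_outcome = FALSE))
  # 2 x approximate SEs of the fixed effects at this design
  se_level <- sqrt(100 / 300)
  se_trend <- sqrt(0.25 / 300)
  expect_lt(abs(fit$alpha[["level"]] - 130), 2 * se_level)
  expect_lt(abs(fit$alpha[["trend"]] + 0.28), 2 * se_trend)
  expect_true(all(abs(diag(fit$G) - c(100, 0.25)) / c(100, 0.25) < 0.30))
  expect_lt(abs(fit$sigma2 - 64) / 64, 0.15)
})

test_that("achieved likelihood beats the generating parameters (dense oracle)", {
  times <- c(0, 2, 6.5, 14)
  set.seed(8)
  G <- diag(c(50, 0.2)); s2 <- 25; alpha <- c(125, -0.3)
  recs <- lapply(1:4, function(i) {
    b <- drop(sbpcourse:::rmvn_psd(1, G))
    y <- drop(polynomial_design(times, 1) %*% (alpha + b)) +
      rnorm(4, 0, sqrt(s2))
    patient_record(paste0("T", i), times, y)
  })
  fit <- suppressWarnings(
    fit_reference_course(sbp_cohort(recs), course_spec(1),
                         fit_config = list(check_outcome = FALSE)))
  ll_truth <- marginal_loglik_dense(recs, alpha, G, s2, 1)
  ll_fit_dense <- marginal_loglik_dense(recs, fit$alpha, fit$G,
                                        fit$sigma2, 1)
  expect_gte(fit$log_likelihood + 1e-6, ll_truth)
  # the reported criterion agrees with the dense evaluation of the fit
  expect_equal(fit$log_likelihood, ll_fit_dense, tolerance = 1e-6)
})

test_that("log-likelihood is non-decreasing in polynomial degree", {
  lls <- vapply(1:3, function(d)
    suppressWarnings(fit_reference_course(
      shared_fav, course_spec(d)))$log_likelihood, numeric(1))
  expect_true(all(diff(lls) > -1e-4 * abs(lls[1])))
})

test_that("fitted marginal covariance is symmetric PSD of the stated form", {
  p <- shared_fav[[1]]
  V <- marginal_covariance(shared_course, p$times)
  Z <- polynomial_design(p$times, 1)
  expect_equal(V, Z %*% shared_course$G %*% t(Z) +
                 diag(shared_course$sigma2, length(p$times)))
  expect_equal(V, t(V))
  expect_true(min(eigen(V, symmetric = TRUE, only.values = TRUE)$values) > 0)
})

test_that("fit is invariant to patient order", {
  set.seed(2)
  perm <- sample(length(shared_fav))
  refit <- suppressWarnings(
    fit_reference_course(shared_fav[perm], course_spec(1)))
  expect_lt(max(abs(refit$alpha - shared_course$alpha)), 1e-6)
  expect_lt(max(abs(refit$G - shared_course$G)), 1e-6)
})

test_that("fit preconditions are enforced", {
  expect_error(fit_reference_course(shared_fav[1:3], course_spec(1)),
               "at least 4 patients")
  unfav <- sbp_cohort(lapply(1:8, function(i) {
    p <- shared_fav[[i]]; p$outcomes$functional_independence <- 0L; p
  }))
  expect_error(fit_reference_course(unfav, course_spec(1)),
               "favourable value")
})

test_that("reference course serializes to JSON and back", {
  path <- withr::local_tempfile(fileext = ".json")
  write_course_json(shared_course, path)
  rc <- read_course_json(path)
  expect_equal(rc$alpha, shared_course$alpha)
  expect_equal(rc$G, shared_course$G)
  expect_equal(rc$sigma2, shared_course$sigma2)
  expect_equal(rc$spec, shared_course$spec)
})
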