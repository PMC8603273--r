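test_that("full adherence yields exactly the scheduled 21 measurements", {
  cfg <- synthetic_config(n_patients = 10, dropout_prob = 0,
                          optional_measurement_prob = 0,
                          force_below_min_frac = 0, seed = 5)
  cohort <- generate_cohort(cfg)
  expect_true(all(vapply(cohort, function(p) length(p$times), integer(1))
                  == 21L))
})

test_that("full adherence plus all optional yields 29 measurements", {
  cfg <- synthetic_config(n_patients = 10, dropout_prob = 0,
                          optional_measurement_prob = 1,
                          force_below_min_frac = 0, seed = 5)
  cohort <- generate_cohort(cfg)
  expect_true(all(vapply(cohort, function(p) length(p$times), integer(1))
                  == 29L))
})

test_that("generation is deterministic in the seed", {
  cfg <- synthetic_config(n_patients = 25, seed = 99)
  expect_identical(generate_cohort(cfg), generate_cohort(cfg))
  other <- generate_cohort(synthetic_config(n_patients = 25, seed = 100))
  expect_false(identical(generate_cohort(cfg), other))
})

test_that("pointwise mean SBP tracks the generating line (n = 500)", {
  cfg <- synthetic_config(n_patients = 500, true_alpha = c(130, -0.28),
                          true_G = diag(c(100, 0.25)), true_sigma2 = 64,
                          dropout_prob = 0, optional_measurement_prob = 0,
                          force_below_min_frac = 0, seed = 11)
  cohort <- generate_cohort(cfg)
  sched <- default_schedule()$scheduled
  sbp_mat <- t(vapply(cohort, function(p) p$sbp, numeric(21)))
  expected <- 130 - 0.28 * sched     # analytic mean of the generative model
  expect_true(all(abs(colMeans(sbp_mat) - expected) < 3))
})

test_that("empirical covariance of the random-effect draws converges to G", {
  G <- matrix(c(100, 2, 2, 0.25), 2)
  cfg <- synthetic_config(n_patients = 5000, true_G = G,
                          force_below_min_frac = 0, seed = 13)
  eff <- attr(generate_cohort(cfg), "true_effects")
  emp <- cov(eff)
  scale <- sqrt(outer(diag(G), diag(G)))
  expect_true(all(abs(emp - G) / scale < 0.10))
})

test_that("outcome prevalence is monotone in the intercept", {
  prev <- vapply(c(-2, 5.1, 12), function(b0) {
    oc <- default_outcome_coefficients(1)
    oc$functional_independence[["intercept"]] <- b0
    cfg <- synthetic_config(n_patients = 200, outcome_coefficients = oc,
                            seed = 21)
    cohort_proportions(generate_cohort(cfg), "functional_independence")
  }, numeric(1))
  expect_true(all(diff(prev) > 0))
})

test_that("invalid configurations are rejected", {
  expect_error(synthetic_config(true_G = matrix(c(1, 2, 2, 1), 2)),
               "positive semidefinite")
  expect_error(synthetic_config(true_G = diag(3)), "2 x 2")
  expect_error(synthetic_config(true_sigma2 = -1), "true_sigma2")
  expect_error(synthetic_config(dropout_prob = 1.5), "probability")
  expect_error(generate_cohort(synthetic_config(n_patients = 1)),
               "n_patients")
})

test_that("synthetic config round-trips through JSON", {
  cfg <- synthetic_config(n_patients = 33, true_G = matrix(c(90, 1, 1, 0.3), 2),
                          seed = 7)
  path <- withr::local_tempfile(fileext = ".json")
  write_synthetic_config(cfg, path)
  cfg2 <- read_synthetic_config(path)
  expect_equal(cfg2$true_G, cfg$true_G)
  expect_equal(cfg2$outcome_coefficients, cfg$outcome_coefficients)
  expect_identical(generate_cohort(cfg2), generate_cohort(cfg))
})
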