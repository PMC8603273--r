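test_that("identity resample with one iteration reproduces point estimates", {
  bs <- bootstrap_pipeline(shared_included, course_spec(1),
                           n_iterations = 1, seed = 9,
                           fit_config = list(restarts = 1L),
                           .identity = TRUE)
  point <- sbpcourse:::pipeline_once(shared_included, course_spec(1),
                                     list(restarts = 1L))
  expect_equal(unname(bs$draws[1, ]),
               point$fit$coefficients$estimate, tolerance = 1e-8)
  # percentile CI of a single draw collapses onto the estimate
  expect_equal(bs$ci$ci_lower, bs$ci$ci_upper, tolerance = 1e-12)
})

test_that("bootstrap is reproducible under a fixed seed", {
  run <- function() suppressWarnings(
    bootstrap_pipeline(shared_included, course_spec(1),
                       n_iterations = 25, seed = 31,
                       fit_config = list(restarts = 1L)))
  b1 <- run(); b2 <- run()
  expect_identical(b1$draws, b2$draws)
  expect_identical(b1$ci, b2$ci)
  expect_identical(b1$n_failed_iterations, b2$n_failed_iterations)
})

test_that("a strong generating trend effect yields a CI excluding zero", {
  oc <- default_outcome_coefficients(1)
  # |beta| * SD(trend effect) = 3 * 0.5 = 1.5 > 1
  oc$functional_independence[["effect_2"]] <- -3
  oc$functional_independence[["intercept"]] <- 5.1
  cfg <- synthetic_config(n_patients = 150, outcome_coefficients = oc,
                          force_below_min_frac = 0, seed = 77)
  cohort <- generate_cohort(cfg)
  included <- apply_inclusion_filter(cohort, window_filter(24))$included
  bs <- suppressWarnings(
    bootstrap_pipeline(included, course_spec(1), n_iterations = 200,
                       seed = 78, fit_config = list(restarts = 1L)))
  ci <- bs$fit$coefficients
  trend <- ci[ci$term == "effect_trend", ]
  expect_lt(trend$ci_upper, 0)
  expect_lt(bs$n_failed_iterations, 20)
})
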