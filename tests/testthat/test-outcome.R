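# Builds an effects-table + covariates pair with a prescribed effect
# column; other covariates drawn once under a fixed seed.
make_tables <- function(n, effect, seed = 1) {
  set.seed(seed)
  ids <- sprintf("M%04d", seq_len(n))
  eff <- data.frame(patient_id = ids, window_hours = 24,
                    n_measurements_used = 21L,
                    effect_level = rnorm(n, 0, 10), effect_trend = effect)
  cov <- data.frame(patient_id = ids, age = round(rnorm(n, 71, 10)),
                    sex = rbinom(n, 1, 0.5),
                    nihss_baseline = sample(0:30, n, replace = TRUE),
                    hypertension = rbinom(n, 1, 0.4),
                    mtici_success = rbinom(n, 1, 0.75))
  list(eff = eff, cov = cov)
}

test_that("a predictor independent of the outcome has OR near 1", {
  n <- 2000
  tb <- make_tables(n, effect = rnorm(n), seed = 2)
  set.seed(3)
  tb$cov$functional_independence <- rbinom(n, 1, 0.5)
  fit <- fit_outcome_model(tb$eff, tb$cov, "functional_independence")
  or <- fit$coefficients$odds_ratio[fit$coefficients$term == "effect_trend"]
  expect_gt(or, 0.9); expect_lt(or, 1.1)
})

test_that("single-binary-predictor fit equals the 2x2 closed form", {
  # exposed: 10 events / 20 non-events; unexposed: 5 / 40 -> OR = 8
  y <- c(rep(1, 10), rep(0, 20), rep(1, 5), rep(0, 40))
  x <- c(rep(1, 30), rep(0, 45))
  n <- length(y)
  eff <- data.frame(patient_id = sprintf("M%04d", 1:n), window_hours = 24,
                    n_measurements_used = 21L, effect_trend = x)
  cov <- data.frame(patient_id = sprintf("M%04d", 1:n), age = 70, sex = 1,
                    nihss_baseline = 10, hypertension = 0,
                    mtici_success = 1, functional_independence = y)
  fit <- fit_outcome_model(eff, cov, "functional_independence")
  or <- fit$coefficients$odds_ratio[fit$coefficients$term == "effect_trend"]
  expect_equal(or, (10 * 40) / (20 * 5), tolerance = 1e-6)
})

test_that("an aliased duplicate column does not perturb the estimates", {
  n <- 300
  tb <- make_tables(n, effect = rnorm(n), seed = 4)
  set.seed(5)
  tb$cov$functional_independence <-
    rbinom(n, 1, plogis(0.5 * tb$eff$effect_trend))
  base_fit <- fit_outcome_model(tb$eff, tb$cov, "functional_independence")
  dup <- tb$eff
  dup$effect_dupe <- dup$effect_trend   # exact copy, new label
  dup_fit <- fit_outcome_model(dup, tb$cov, "functional_independence")
  shared <- base_fit$coefficients$term
  m <- match(shared, dup_fit$coefficients$term)
  expect_equal(dup_fit$coefficients$estimate[m],
               base_fit$coefficients$estimate, tolerance = 1e-8)
})

test_that("model preconditions and separation are reported", {
  n <- 30
  tb <- make_tables(n, effect = rnorm(n), seed = 6)
  tb$cov$functional_independence <- c(rep(1, 25), rep(0, 5))
  expect_error(fit_outcome_model(tb$eff, tb$cov, "functional_independence"),
               "10 events")
  n <- 60
  tb <- make_tables(n, effect = c(rnorm(30, -8), rnorm(30, 8)), seed = 7)
  tb$cov$functional_independence <- rep(c(0, 1), each = 30)
  expect_error(fit_outcome_model(tb$eff, tb$cov, "functional_independence"),
               "effect_trend")
})

test_that("AUC agrees with the exhaustive pairwise definition", {
  expect_equal(compute_auc(c(1, 2, 3, 4), c(0, 0, 1, 1)), 1.0)
  expect_equal(compute_auc(rep(2, 6), c(0, 1, 0, 1, 1, 0)), 0.5)
  expect_equal(compute_auc(c(3, 1, 2, 4, 2), c(1, 0, 0, 1, 1)), 5.5 / 6)
  expect_error(compute_auc(1:4, c(1, 1, 1, 1)), "both classes")
  set.seed(10)
  for (rep in 1:50) {
    n <- sample(4:40, 1)
    s <- sample(0:8, n, replace = TRUE)
    l <- rbinom(n, 1, 0.5)
    if (length(unique(l)) < 2) next
    expect_equal(compute_auc(s, l), pairwise_auc_oracle(s, l))
    # invariance under strictly increasing transforms
    expect_equal(compute_auc(exp(s / 3), l), compute_auc(s, l))
  }
})

test_that("cohort proportions use the full registered denominator", {
  labels <- c(rep(1L, 169), rep(0L, 175), rep(NA_integer_, 30))
  cohort <- counted_cohort(rep(21L, 374), labels = labels)
  expect_equal(cohort_proportions(cohort, "functional_independence"), 45.2)
  none <- counted_cohort(rep(21L, 50), labels = rep(0L, 50))
  expect_equal(cohort_proportions(none, "functional_independence"), 0)
  expect_error(cohort_proportions(sbp_cohort(list()),
                                  "functional_independence"), "empty")
})

test_that("zeroed deviations degrade the model to covariates only", {
  eff <- eblup_table(shared_included, shared_course, 24)
  covs <- cohort_table(shared_included)
  eff0 <- eff
  eff0[grep("^effect_", names(eff0))] <- 0
  fit0 <- fit_outcome_model(eff0, covs, "functional_independence")
  keep <- complete.cases(covs[c("age", "sex", "nihss_baseline",
                                "hypertension", "mtici_success",
                                "functional_independence")])
  ref <- glm(functional_independence ~ age + sex + nihss_baseline +
               hypertension + mtici_success,
             data = covs[keep, ], family = binomial())
  expect_equal(compute_auc(fit0$scores, fit0$labels),
               compute_auc(ref$linear.predictors,
                           covs$functional_independence[keep]))
})
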