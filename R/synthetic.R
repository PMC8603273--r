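#' Configuration for the synthetic post-EVT cohort generator
#'
#' Describes the generative model mirrored on the analysis model: a
#' population polynomial SBP course (`true_alpha`), patient-level random
#' coefficients drawn from `MVN(0, true_G)`, i.i.d. residual noise
#' `N(0, true_sigma2)`, the monitoring protocol with optional measurements
#' and dropout, and logistic outcome labels driven by the random effects
#' and baseline covariates.
#'
#' Covariates are drawn from fixed marginal distributions chosen to match
#' a typical large-artery-occlusion thrombectomy cohort: age truncated
#' normal (mean 71, SD 13, range 18-100); baseline NIHSS a rounded
#' Gamma(shape 4, scale 4.085) clamped to 0-42 (median about 15, IQR about
#' 10-20); sex, hypertension history and successful recanalisation
#' Bernoulli with probabilities 0.532, 0.436 and 0.736.
#'
#' @param n_patients Number of patients (>= 2). Default 374.
#' @param true_alpha Fixed-effect vector (level mm Hg, trend mm Hg/h, and
#'   optionally curvature mm Hg/h^2, twist mm Hg/h^3). Length sets the
#'   polynomial degree. Default `c(130, -0.28)`.
#' @param true_G Random-effects covariance matrix, symmetric PSD with
#'   dimension `length(true_alpha)`. Default `diag(c(100, 0.25))`
#'   (between-patient SD 10 mm Hg in level, 0.5 mm Hg/h in trend).
#' @param true_sigma2 Residual variance in mm Hg^2 (> 0). Default 64.
#' @param outcome_coefficients Named list, one numeric vector per outcome
#'   label, each with elements `intercept`, `effect_1..effect_q`
#'   (coefficients on the random effects), `age`, `sex`, `nihss_baseline`,
#'   `hypertension`, `mtici_success`. See
#'   [default_outcome_coefficients()].
#' @param optional_measurement_prob Probability each optional odd-hour
#'   measurement is recorded. Default 0.25.
#' @param dropout_prob Probability each scheduled measurement is missing.
#'   Default 0.08.
#' @param force_below_min_frac Fraction of patients forced below 10
#'   measurements in 24 h (to exercise the inclusion filter). Default
#'   0.155.
#' @param jitter_minutes Half-width of uniform timestamp jitter in
#'   minutes; 0 (default) keeps exact protocol times.
#' @param seed Master RNG seed; per-patient substreams are derived from it.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_patients = 374,
                             true_alpha = c(130, -0.28),
                             true_G = diag(c(100, 0.25)),
                             true_sigma2 = 64,
                             outcome_coefficients =
                               default_outcome_coefficients(length(true_alpha) - 1),
                             optional_measurement_prob = 0.25,
                             dropout_prob = 0.08,
                             force_below_min_frac = 0.155,
                             jitter_minutes = 0,
                             seed = 1L) {
  cfg <- structure(list(
    n_patients = as.integer(n_patients),
    true_alpha = as.numeric(true_alpha),
    true_G = as.matrix(true_G),
    true_sigma2 = as.numeric(true_sigma2),
    outcome_coefficients = outcome_coefficients,
    optional_measurement_prob = as.numeric(optional_measurement_prob),
    dropout_prob = as.numeric(dropout_prob),
    force_below_min_frac = as.numeric(force_below_min_frac),
    jitter_minutes = as.numeric(jitter_minutes),
    seed = as.integer(seed)
  ), class = "synthetic_config")
  validate_synthetic_config(cfg)
  cfg
}

validate_synthetic_config <- function(cfg) {
  q <- length(cfg$true_alpha)
  if (q < 2 || q > 4)
    stop_sbp("true_alpha must have length 2-4 (degree 1-3)")
  G <- cfg$true_G
  if (!is.matrix(G) || nrow(G) != q || ncol(G) != q)
    stop_sbp("true_G must be a %d x %d matrix to match true_alpha", q, q)
  if (max(abs(G - t(G))) > 1e-8 * (1 + max(abs(G))))
    stop_sbp("true_G must be symmetric")
  ev <- eigen(G, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev), 1))
    stop_sbp("true_G must be positive semidefinite (min eigenvalue %.3g)",
             min(ev))
  if (cfg$true_sigma2 <= 0) stop_sbp("true_sigma2 must be > 0")
  for (p in c("optional_measurement_prob", "dropout_prob",
              "force_below_min_frac")) {
    v <- cfg[[p]]
    if (!is.numeric(v) || v < 0 || v > 1)
      stop_sbp("%s must be a probability in [0, 1]", p)
  }
  bad <- setdiff(names(cfg$outcome_coefficients), outcome_names())
  if (length(bad))
    stop_sbp("unknown outcome(s) in outcome_coefficients: %s",
             paste(bad, collapse = ", "))
  invisible(cfg)
}

#' Default generative outcome coefficients
#'
#' Logistic coefficients linking each binary outcome label to the
#' patient's random-effect deviations and baseline covariates. The
#' functional-independence label carries the SBP-course signal (negative
#' weight on the trend deviation: veering off the reference slope lowers
#' the chance of independence) plus the usual prognostic covariates;
#' the other labels are predominantly covariate-driven. Intercepts were
#' fixed once, analytically, so that marginal prevalences approximate
#' 45\%, 78\%, 95\% and 86\% under the default covariate distributions.
#'
#' @param degree Polynomial degree of the generative course (1-3);
#'   coefficients for random-effect components beyond the trend default
#'   to zero.
#' @return Named list of coefficient vectors, one per outcome label.
#' @export
default_outcome_coefficients <- function(degree = 1) {
  q <- degree + 1
  base <- function(intercept, eff, age, sex, nihss, ht, mtici) {
    eff <- c(eff, rep(0, q - length(eff)))[seq_len(q)]
    c(intercept = intercept, setNames(eff, paste0("effect_", seq_len(q))),
      age = age, sex = sex, nihss_baseline = nihss, hypertension = ht,
      mtici_success = mtici)
  }
  list(
    functional_independence =
      base(5.1, c(-0.05, -0.8), -0.06, 0.5, -0.12, -0.3, 1.0),
    alive = base(7.7, c(-0.03, -0.4), -0.07, 0.0, -0.10, -0.2, 0.8),
    no_sich = base(3.5, c(-0.02, -0.2), 0.0, 0.0, -0.05, 0.0, 0.5),
    no_ich = base(3.4, c(-0.03, -0.3), -0.01, 0.0, -0.06, 0.0, 0.3)
  )
}

# Draw from MVN(0, G) for PSD (possibly singular) G via eigendecomposition.
rmvn_psd <- function(n, G) {
  q <- nrow(G)
  e <- eigen(G, symmetric = TRUE)
  lam <- pmax(e$values, 0)
  z <- matrix(rnorm(n * q), n, q)
  z %*% (t(e$vectors) * sqrt(lam))
}

draw_covariates <- function() {
  age <- rnorm(1, 71, 13)
  while (age < 18 || age > 100) age <- rnorm(1, 71, 13)
  nihss <- min(max(round(rgamma(1, shape = 4, scale = 4.085)), 0L), 42L)
  list(age = age,
       sex = rbinom(1, 1, 0.532),
       nihss_baseline = as.integer(nihss),
       hypertension = rbinom(1, 1, 0.436),
       mtici_success = rbinom(1, 1, 0.736))
}

#' Generate a synthetic post-EVT cohort
#'
#' Simulates one cohort under the generative model in
#' [synthetic_config()]: per patient, a random-coefficient deviation from
#' the population course, SBP measurements at the retained protocol times
#' with residual noise, baseline covariates, and Bernoulli outcome labels
#' from the logistic outcome model. Per-patient RNG substreams are derived
#' from the master seed, so the same configuration always yields the same
#' cohort regardless of generation order.
#'
#' @param config A [synthetic_config()].
#' @return An [sbp_cohort()] with attribute `"true_effects"`: the matrix
#'   of generating random-effect draws (one row per patient).
#' @examples
#' cohort <- generate_cohort(synthetic_config(n_patients = 20, seed = 7))
#' length(cohort)
#' @export
generate_cohort <- function(config) {
  validate_synthetic_config(config)
  if (config$n_patients < 2) stop_sbp("n_patients must be >= 2")
  q <- length(config$true_alpha)
  sched <- default_schedule()
  records <- vector("list", config$n_patients)
  effects <- matrix(NA_real_, config$n_patients, q)

  for (i in seq_len(config$n_patients)) {
    set.seed(derive_seed(config$seed, i, stream = 1L))
    b <- drop(rmvn_psd(1, config$true_G))
    effects[i, ] <- b
    cov <- draw_covariates()

    keep_sched <- sched$scheduled[
      runif(length(sched$scheduled)) >= config$dropout_prob]
    keep_opt <- sched$optional[
      runif(length(sched$optional)) < config$optional_measurement_prob]
    times <- sort(c(keep_sched, keep_opt))
    forced_low <- runif(1) < config$force_below_min_frac
    if (forced_low && length(times) >= 10) {
      n_keep <- sample(3:9, 1)
      times <- sort(sample(times, n_keep))
    }
    if (config$jitter_minutes > 0 && length(times)) {
      jit <- runif(length(times), -config$jitter_minutes,
                   config$jitter_minutes) / 60
      times <- sort(pmin(pmax(times + jit, 0), 24))
      times <- times[c(TRUE, diff(times) > 1e-9)]
    }

    if (length(times)) {
      mu <- drop(polynomial_design(times, q - 1) %*% (config$true_alpha + b))
      sbp <- pmax(mu + rnorm(length(times), 0, sqrt(config$true_sigma2)), 30)
    } else {
      sbp <- numeric(0)
    }

    outc <- list()
    for (nm in outcome_names()) {
      beta <- config$outcome_coefficients[[nm]]
      if (is.null(beta)) { outc[[nm]] <- NA_integer_; next }
      lp <- beta[["intercept"]] +
        sum(beta[paste0("effect_", seq_len(q))] * b) +
        beta[["age"]] * cov$age + beta[["sex"]] * cov$sex +
        beta[["nihss_baseline"]] * cov$nihss_baseline +
        beta[["hypertension"]] * cov$hypertension +
        beta[["mtici_success"]] * cov$mtici_success
      outc[[nm]] <- rbinom(1, 1, plogis(lp))
    }

    records[[i]] <- patient_record(
      patient_id = sprintf("P%04d", i), times = times, sbp = sbp,
      age = cov$age, sex = cov$sex, nihss_baseline = cov$nihss_baseline,
      hypertension = cov$hypertension, mtici_success = cov$mtici_success,
      outcomes = outc)
  }
  cohort <- sbp_cohort(records)
  rownames(effects) <- names(cohort)
  attr(cohort, "true_effects") <- effects
  attr(cohort, "config") <- config
  cohort
}

#' Write or read a synthetic configuration as JSON
#' @param config A `synthetic_config`.
#' @param path File path.
#' @export
write_synthetic_config <- function(config, path) {
  validate_synthetic_config(config)
  x <- unclass(config)
  x$true_G <- as.vector(t(x$true_G))        # row-major
  x$G_dim <- nrow(config$true_G)
  # named vectors must travel as JSON objects, not bare arrays
  x$outcome_coefficients <- lapply(x$outcome_coefficients, as.list)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_synthetic_config
#' @export
read_synthetic_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  q <- x$G_dim
  oc <- lapply(x$outcome_coefficients, function(v) unlist(v))
  synthetic_config(
    n_patients = x$n_patients, true_alpha = x$true_alpha,
    true_G = matrix(x$true_G, q, q, byrow = TRUE),
    true_sigma2 = x$true_sigma2, outcome_coefficients = oc,
    optional_measurement_prob = x$optional_measurement_prob,
    dropout_prob = x$dropout_prob,
    force_below_min_frac = x$force_below_min_frac,
    jitter_minutes = x$jitter_minutes, seed = x$seed)
}
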