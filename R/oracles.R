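#' Brute-force oracles for the pipeline's core linear algebra
#'
#' These functions re-derive quantities the fast paths compute, by
#' independent, deliberately naive routes: dense joint-normal
#' conditioning for the EBLUP, exhaustive pair enumeration for the AUC,
#' and direct dense evaluation of the marginal likelihood. They exist for
#' validation and are exercised by the test-suite; they are not meant to
#' be fast.
#'
#' @name oracles
NULL

#' @describeIn oracles EBLUP as a multivariate-normal conditional mean.
#'   Builds the full `(n_i + degree + 1)`-dimensional joint normal of
#'   `(q_i, b_i)` implied by the course parameters and returns
#'   `E[b_i | q_i]` by generic dense linear algebra (LU solve, no
#'   Cholesky shortcut).
#' @param patient A `patient_record`.
#' @param course A fitted `reference_course`.
#' @param window_hours Monitoring window (default 24).
#' @export
mvn_conditional_oracle <- function(patient, course, window_hours = 24) {
  stopifnot(inherits(patient, "patient_record"),
            inherits(course, "reference_course"), !is.null(course$G))
  p <- truncate_window(patient, window_hours)
  if (!length(p$times)) stop_sbp("no in-window measurements")
  Z <- polynomial_design(p$times, course$spec$degree)
  n <- nrow(Z); q <- ncol(Z)
  G <- course$G
  # joint covariance of (q_i, b_i)
  top <- cbind(Z %*% G %*% t(Z) + diag(course$sigma2, n), Z %*% G)
  bot <- cbind(G %*% t(Z), G)
  V <- rbind(top, bot)
  r <- p$sbp - drop(Z %*% course$alpha)
  mu_cond <- V[(n + 1):(n + q), 1:n, drop = FALSE] %*%
    solve(V[1:n, 1:n, drop = FALSE], r)
  setNames(drop(mu_cond), coef_names(course$spec$degree))
}

#' @describeIn oracles Conditional covariance of the random effects given
#'   the in-window data (used to check that more measurements never make
#'   an effect component less certain).
#' @export
mvn_conditional_variance <- function(patient, course, window_hours = 24) {
  stopifnot(inherits(course, "reference_course"), !is.null(course$G))
  p <- truncate_window(patient, window_hours)
  if (!length(p$times)) stop_sbp("no in-window measurements")
  Z <- polynomial_design(p$times, course$spec$degree)
  G <- course$G
  V11 <- Z %*% G %*% t(Z) + diag(course$sigma2, nrow(Z))
  G - G %*% t(Z) %*% solve(V11, Z %*% G)
}

#' @describeIn oracles AUC by exhaustive enumeration of all
#'   positive-negative pairs, 1/2 credit per tie.
#' @param scores,labels As in [compute_auc()].
#' @export
pairwise_auc_oracle <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  if (!length(pos) || !length(neg))
    stop_sbp("both classes must be present")
  total <- 0
  for (a in pos) for (b in neg)
    total <- total + if (a > b) 1 else if (a == b) 0.5 else 0
  total / (length(pos) * length(neg))
}

#' @describeIn oracles Marginal log-likelihood of course parameters on a
#'   set of patients, evaluated per patient from the dense
#'   `n_i x n_i` multivariate-normal density (no profiling, no
#'   Woodbury) — the independent check on the optimiser's criterion.
#' @param patients List of `patient_record`s.
#' @param alpha,G,sigma2 Course parameters.
#' @param degree Polynomial degree.
#' @export
marginal_loglik_dense <- function(patients, alpha, G, sigma2, degree) {
  ll <- 0
  for (p in patients) {
    Z <- polynomial_design(p$times, degree)
    V <- Z %*% G %*% t(Z) + diag(sigma2, nrow(Z))
    r <- p$sbp - drop(Z %*% alpha)
    ll <- ll - 0.5 * (length(r) * log(2 * pi) +
                        determinant(V, logarithm = TRUE)$modulus +
                        drop(crossprod(r, solve(V, r))))
  }
  as.numeric(ll)
}

#' Parameter-recovery study for the course fit
#'
#' Simulates cohorts from known parameters over a grid of (cohort size,
#' degree) cells and summarises bias and RMSE of the fitted fixed
#' effects, G diagonal and residual variance across replicates.
#'
#' @param grid data.frame with columns `n_patients` and `degree`.
#' @param n_replicates Replicates per cell.
#' @param seed Master seed.
#' @param true_alpha,true_G,true_sigma2 Generating values (defaults as in
#'   [synthetic_config()]); for degree > 1 supply matching dimensions.
#' @param out_csv Optional path to write the summary as CSV.
#' @return data.frame, one row per cell and parameter, with columns
#'   `n_patients`, `degree`, `parameter`, `truth`, `bias`, `rmse`,
#'   `n_converged`, `flag_nonconvergence` (TRUE when > 20% of replicates
#'   failed).
#' @export
parameter_recovery_study <- function(grid, n_replicates = 20, seed = 1L,
                                     true_alpha = c(130, -0.28),
                                     true_G = diag(c(100, 0.25)),
                                     true_sigma2 = 64,
                                     out_csv = NULL) {
  rows <- list()
  for (g in seq_len(nrow(grid))) {
    n_pat <- grid$n_patients[g]; degree <- grid$degree[g]
    q <- degree + 1L
    stopifnot(length(true_alpha) == q)
    est <- list()
    n_conv <- 0L
    for (r in seq_len(n_replicates)) {
      cfg <- synthetic_config(
        n_patients = n_pat, true_alpha = true_alpha, true_G = true_G,
        true_sigma2 = true_sigma2, force_below_min_frac = 0,
        seed = derive_seed(seed, g * 1000L + r, stream = 3L))
      cohort <- generate_cohort(cfg)
      fit <- tryCatch(
        fit_reference_course(cohort, course_spec(degree),
                             fit_config = list(check_outcome = FALSE)),
        error = function(e) NULL)
      if (is.null(fit)) next
      n_conv <- n_conv + 1L
      est[[length(est) + 1L]] <- c(fit$alpha, diag(fit$G), fit$sigma2)
    }
    truth <- c(true_alpha, diag(true_G), true_sigma2)
    pnames <- c(coef_names(degree), paste0("G_", coef_names(degree)),
                "sigma2")
    M <- do.call(rbind, est)
    for (k in seq_along(pnames)) {
      rows[[length(rows) + 1L]] <- data.frame(
        n_patients = n_pat, degree = degree, parameter = pnames[k],
        truth = truth[k],
        bias = if (n_conv) mean(M[, k]) - truth[k] else NA_real_,
        rmse = if (n_conv) sqrt(mean((M[, k] - truth[k])^2)) else NA_real_,
        se_mean = if (n_conv > 1) sd(M[, k]) / sqrt(n_conv) else NA_real_,
        n_converged = n_conv,
        flag_nonconvergence = n_conv < 0.8 * n_replicates,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (!is.null(out_csv)) write.csv(out, out_csv, row.names = FALSE)
  out
}
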