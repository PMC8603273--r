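#' Polynomial design matrix for a measurement-time vector
#'
#' Column k + 1 is `times^k`, k = 0..degree, so the first column is all
#' ones (the level), then trend, curvature and twist columns as the degree
#' allows. The same matrix plays the role of both the fixed-effects and
#' the random-effects design.
#'
#' @param times Numeric vector of measurement times in hours, within
#'   \[0, 24\]; must be non-empty.
#' @param degree Polynomial degree, 1, 2 or 3.
#' @return A `length(times) x (degree + 1)` matrix of exact powers.
#' @examples
#' polynomial_design(c(0, 24), 2)
#' @export
polynomial_design <- function(times, degree) {
  if (!length(times)) stop_sbp("times must be non-empty")
  if (!(degree %in% 1:3)) stop_sbp("degree must be 1, 2 or 3")
  if (any(times < 0 | times > 24))
    stop_sbp("times must lie within [0, 24] hours")
  outer(as.numeric(times), 0:degree, `^`)
}

coef_names <- function(degree) {
  c("level", "trend", "curvature", "twist")[seq_len(degree + 1)]
}

#' Course specification: polynomial degree and target outcome
#'
#' @param degree 1 (linear), 2 (quadratic) or 3 (cubic).
#' @param outcome_name One of `functional_independence`, `alive`,
#'   `no_sich`, `no_ich`; the reference course is fit on patients with
#'   the favourable (= 1) value of this label.
#' @return A `course_spec` object.
#' @export
course_spec <- function(degree, outcome_name = "functional_independence") {
  if (!(degree %in% 1:3)) stop_sbp("degree must be 1, 2 or 3")
  outcome_name <- match.arg(outcome_name, outcome_names())
  structure(list(degree = as.integer(degree), outcome_name = outcome_name),
            class = "course_spec")
}

#' Construct a reference SBP course object
#'
#' Usually produced by [fit_reference_course()]; this constructor also
#' lets worked examples build a course directly from reported
#' fixed-effect estimates (`G` and `sigma2` may then be omitted, which
#' disables EBLUP projection but not course evaluation).
#'
#' @param spec A [course_spec()].
#' @param alpha Fixed-effects vector, length `degree + 1`
#'   (level mm Hg, trend mm Hg/h, curvature mm Hg/h^2, twist mm Hg/h^3).
#' @param G Random-effects covariance matrix (symmetric PSD, strictly
#'   positive diagonal), or `NULL`.
#' @param sigma2 Residual variance mm Hg^2 (> 0), or `NA`.
#' @param log_likelihood Achieved fit criterion, or `NA`.
#' @param n_patients_fit Number of patients used in the fit.
#' @param boundary Logical flag: a variance component was estimated at
#'   (numerically) zero.
#' @return A `reference_course` object.
#' @export
reference_course <- function(spec, alpha, G = NULL, sigma2 = NA_real_,
                             log_likelihood = NA_real_,
                             n_patients_fit = NA_integer_,
                             boundary = FALSE) {
  stopifnot(inherits(spec, "course_spec"))
  q <- spec$degree + 1L
  alpha <- as.numeric(alpha)
  if (length(alpha) != q)
    stop_sbp("alpha must have length %d for degree %d", q, spec$degree)
  names(alpha) <- coef_names(spec$degree)
  if (!is.null(G)) {
    G <- as.matrix(G)
    if (nrow(G) != q || ncol(G) != q) stop_sbp("G must be %d x %d", q, q)
    if (max(abs(G - t(G))) > 1e-6 * (1 + max(abs(G))))
      stop_sbp("G must be symmetric")
    ev <- eigen((G + t(G)) / 2, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-6 * max(abs(ev), 1))
      stop_sbp("G must be positive semidefinite")
    if (any(diag(G) <= 0))
      stop_sbp("diagonal of G must be strictly positive")
    dimnames(G) <- list(coef_names(spec$degree), coef_names(spec$degree))
    if (!is.na(sigma2) && sigma2 <= 0) stop_sbp("sigma2 must be > 0")
  }
  structure(list(spec = spec, alpha = alpha, G = G, sigma2 = sigma2,
                 log_likelihood = log_likelihood,
                 n_patients_fit = n_patients_fit, boundary = boundary),
            class = "reference_course")
}

#' Evaluate a reference SBP course at given times
#'
#' The population course at time `t` is the polynomial in the fixed
#' effects alone (zero random effects, zero residual).
#'
#' @param course A `reference_course`.
#' @param t Hours since end of EVT, within \[0, 24\] (the modelled
#'   window; extrapolation is refused).
#' @return SBP in mm Hg (vectorised over `t`).
#' @examples
#' rc <- reference_course(course_spec(1), alpha = c(129.78, -0.28378))
#' evaluate_course(rc, c(0, 24))
#' @export
evaluate_course <- function(course, t) {
  stopifnot(inherits(course, "reference_course"))
  if (any(t < 0 | t > 24))
    stop_sbp("t outside [0, 24]: the course is not modelled beyond 24 h")
  drop(polynomial_design(t, course$spec$degree) %*% course$alpha)
}

# Per-patient sufficient statistics for the marginal likelihood:
# Z'Z, Z'y, y'y, n. All likelihood evaluations run off these.
suff_stats <- function(patients, degree) {
  szz <- vector("list", length(patients))
  szy <- vector("list", length(patients))
  syy <- numeric(length(patients))
  nobs <- integer(length(patients))
  for (i in seq_along(patients)) {
    p <- patients[[i]]
    Z <- polynomial_design(p$times, degree)
    szz[[i]] <- crossprod(Z)
    szy[[i]] <- drop(crossprod(Z, p$sbp))
    syy[i] <- sum(p$sbp^2)
    nobs[i] <- length(p$times)
  }
  list(szz = szz, szy = szy, syy = syy, nobs = nobs)
}

# Pack/unpack the lower-triangular relative Cholesky factor
# (log-diagonal) used as the unconstrained optimisation parameter.
lambda_to_theta <- function(L) {
  q <- nrow(L)
  th <- numeric(0)
  for (j in seq_len(q)) {
    d <- L[j, j]
    th <- c(th, log(max(d, 1e-8)), if (j < q) L[(j + 1):q, j])
  }
  th
}

theta_dim <- function(q) q * (q + 1) / 2

# Starting values from per-patient OLS: relative covariance of the OLS
# coefficients, shrunk towards a diagonal, over a pooled residual variance.
start_theta <- function(patients, degree, stats) {
  q <- degree + 1L
  usable <- which(stats$nobs >= q + 2L)
  coefs <- NULL
  rss <- 0; dfres <- 0
  for (i in usable) {
    Z <- polynomial_design(patients[[i]]$times, degree)
    fit <- tryCatch(lm.fit(Z, patients[[i]]$sbp), error = function(e) NULL)
    if (is.null(fit) || any(is.na(fit$coefficients))) next
    coefs <- rbind(coefs, fit$coefficients)
    rss <- rss + sum(fit$residuals^2)
    dfres <- dfres + length(fit$residuals) - q
  }
  s2 <- if (dfres > 0) max(rss / dfres, 1e-4) else 1
  if (is.null(coefs) || nrow(coefs) < 3) {
    Gstar <- diag(q) * 0.5
  } else {
    Graw <- stats::cov(coefs)
    # OLS coefficient scatter overstates G (it includes sampling noise);
    # keep only the diagonal, floored, as a robust relative start.
    Gstar <- diag(pmax(diag(Graw) / s2 * 0.5, 1e-4), q)
  }
  L <- t(chol(Gstar))
  list(theta = lambda_to_theta(L), s2 = s2)
}

#' Fit a reference SBP course by maximum likelihood
#'
#' Fits the polynomial random-coefficient model
#' `SBP_ij = (alpha + b_i)' z(t_ij) + e_ij`, `b_i ~ MVN(0, G)`,
#' `e_ij ~ N(0, sigma2)`, with a random effect on every coefficient
#' including the intercept, on the supplied patients (normally the
#' favourable-outcome subcohort after the inclusion filter). The marginal
#' likelihood is profiled over the fixed effects and the residual
#' variance and maximised by quasi-Newton over the Cholesky factor of
#' `G / sigma2` (log-scale diagonal), which enforces positive
#' semidefiniteness and a positive diagonal by construction. Several
#' restarts guard against local optima of the variance-component surface.
#'
#' @param favorable_patients An [sbp_cohort()] (or list of
#'   `patient_record`s) of reference-population patients.
#' @param spec A [course_spec()]. If outcome labels are present, every
#'   patient must carry the favourable (= 1) value of
#'   `spec$outcome_name`.
#' @param fit_config List: `method` ("ML", default, or "REML"),
#'   `restarts` (default 3), `reltol` (default 1e-10), `maxit`
#'   (default 500).
#' @return A `reference_course` with fitted `alpha`, `G`, `sigma2`, the
#'   achieved `log_likelihood` (criterion / -2 for REML), and a
#'   `boundary` flag for variance estimates at numerically zero (reported
#'   with a warning, not an error).
#' @export
fit_reference_course <- function(favorable_patients, spec,
                                 fit_config = list()) {
  stopifnot(inherits(spec, "course_spec"))
  fc <- modifyList(list(method = "ML", restarts = 3L, reltol = 1e-10,
                        maxit = 500L, check_outcome = TRUE), fit_config)
  patients <- unclass(favorable_patients)
  q <- spec$degree + 1L
  if (length(patients) < 2 * q)
    stop_sbp("need at least %d patients to fit a degree-%d course, got %d",
             2 * q, spec$degree, length(patients))
  if (isTRUE(fc$check_outcome)) {
    lab <- vapply(patients, function(p) {
      v <- p$outcomes[[spec$outcome_name]]
      if (is.null(v)) NA_integer_ else as.integer(v)
    }, integer(1))
    if (any(!is.na(lab) & lab != 1L))
      stop_sbp("fit population must carry the favourable value of '%s'",
               spec$outcome_name)
  }
  if (any(vapply(patients, function(p) length(p$times), integer(1)) < 1))
    stop_sbp("every patient must have at least one SBP measurement")

  stats <- suff_stats(patients, spec$degree)
  reml <- identical(toupper(fc$method), "REML")
  objective <- function(theta) {
    r <- .cpp_profiled_deviance(theta, stats$szz, stats$szy, stats$syy,
                                stats$nobs, reml)
    r$deviance
  }

  st <- start_theta(patients, spec$degree, stats)
  starts <- list(st$theta)
  scales <- c(0.4, 2.5, 0.1)
  diag_idx <- cumsum(c(1, rev(seq_len(q - 1) + 1)))[seq_len(q)]
  for (k in seq_len(max(fc$restarts - 1L, 0L))) {
    th <- st$theta
    th[diag_idx] <- th[diag_idx] + log(scales[(k - 1L) %% 3L + 1L])
    starts[[k + 1L]] <- th
  }
  if (spec$degree > 1L) {
    # warm start embedding the next-lower-degree solution, so the
    # achieved likelihood is monotone in polynomial degree
    low <- tryCatch(
      fit_reference_course(patients, course_spec(spec$degree - 1L,
                                                 spec$outcome_name),
                           modifyList(fc, list(check_outcome = FALSE,
                                               restarts = 2L))),
      error = function(e) NULL)
    if (!is.null(low)) {
      Gs <- matrix(0, q, q)
      Gs[seq_len(q - 1), seq_len(q - 1)] <- low$G / low$sigma2
      # tiny new component, scaled so its contribution at t = 24 h is
      # ~1e-6 * sigma2 (the t^k columns span wildly different magnitudes)
      Gs[q, q] <- 1e-6 / 24^(2 * (q - 1))
      Lw <- tryCatch(t(chol(Gs + diag(1e-12 * diag(Gs) + 1e-15))),
                     error = function(e) NULL)
      if (!is.null(Lw)) starts[[length(starts) + 1L]] <- lambda_to_theta(Lw)
    }
  }

  best <- NULL; codes <- integer(0)
  for (th0 in starts) {
    opt <- tryCatch(
      optim(th0, objective, method = "BFGS",
            control = list(reltol = fc$reltol, maxit = fc$maxit)),
      error = function(e) NULL)
    if (is.null(opt)) { codes <- c(codes, -1L); next }
    codes <- c(codes, opt$convergence)
    if (opt$convergence != 0) next
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (is.null(best))
    stop_sbp(paste0("reference-course fit did not converge after %d ",
                    "restarts (optim codes: %s)"),
             length(starts), paste(codes, collapse = ", "))

  r <- .cpp_profiled_deviance(best$par, stats$szz, stats$szy, stats$syy,
                              stats$nobs, reml)
  L <- r$lambda
  G <- r$sigma2 * tcrossprod(L)
  boundary <- any(diag(G) < 1e-6 * r$sigma2)
  if (boundary)
    warn_sbp("variance component estimated at the zero boundary")
  # floor the diagonal so downstream linear algebra sees a valid G
  diag(G) <- pmax(diag(G), 1e-10 * max(r$sigma2, 1))

  reference_course(spec = spec, alpha = r$alpha, G = G, sigma2 = r$sigma2,
                   log_likelihood = -r$deviance / 2,
                   n_patients_fit = length(patients), boundary = boundary)
}

#' Marginal covariance of one patient's measurements under a course
#'
#' `Z G Z' + sigma2 I`, the model-implied covariance of the observed SBP
#' vector; symmetric positive definite whenever `sigma2 > 0`.
#' @param course A fitted `reference_course` (with `G`, `sigma2`).
#' @param times Measurement times in hours.
#' @return A square covariance matrix.
#' @export
marginal_covariance <- function(course, times) {
  stopifnot(inherits(course, "reference_course"), !is.null(course$G))
  Z <- polynomial_design(times, course$spec$degree)
  Z %*% course$G %*% t(Z) + diag(course$sigma2, length(times))
}

#' @export
print.reference_course <- function(x, ...) {
  cat(sprintf("Reference SBP course (degree %d, favourable '%s')\n",
              x$spec$degree, x$spec$outcome_name))
  cat("  fixed effects:",
      paste(sprintf("%s = %.4g", names(x$alpha), x$alpha), collapse = ", "),
      "\n")
  if (!is.null(x$G)) {
    cat(sprintf("  residual variance: %.4g mm Hg^2\n", x$sigma2))
    cat(sprintf("  G diagonal: %s\n",
                paste(sprintf("%.4g", diag(x$G)), collapse = ", ")))
  }
  if (!is.na(x$log_likelihood))
    cat(sprintf("  log-likelihood: %.3f (n = %d patients)\n",
                x$log_likelihood, x$n_patients_fit))
  if (isTRUE(x$boundary)) cat("  note: boundary (zero-variance) fit\n")
  invisible(x)
}

#' Serialize a reference course to / from JSON
#'
#' Stores `alpha`, `G` (row-major), `sigma2`, the spec and fit metadata,
#' so EBLUP projection can run without refitting.
#' @param course A `reference_course`.
#' @param path JSON file path.
#' @export
write_course_json <- function(course, path) {
  stopifnot(inherits(course, "reference_course"))
  x <- list(degree = course$spec$degree,
            outcome_name = course$spec$outcome_name,
            alpha = unname(course$alpha),
            G = if (is.null(course$G)) NULL else as.vector(t(course$G)),
            sigma2 = course$sigma2,
            log_likelihood = course$log_likelihood,
            n_patients_fit = course$n_patients_fit,
            boundary = course$boundary)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_course_json
#' @export
read_course_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  q <- x$degree + 1
  reference_course(
    spec = course_spec(x$degree, x$outcome_name),
    alpha = x$alpha,
    G = if (is.null(x$G)) NULL else matrix(x$G, q, q, byrow = TRUE),
    sigma2 = x$sigma2 %||% NA_real_,
    log_likelihood = x$log_likelihood %||% NA_real_,
    n_patients_fit = x$n_patients_fit %||% NA_integer_,
    boundary = isTRUE(x$boundary))
}
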