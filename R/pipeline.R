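#' Run configuration for the end-to-end pipeline
#'
#' @param sbp_csv,covariate_csv Input CSVs ([read_cohort()]); omit both
#'   to simulate instead.
#' @param synthetic A [synthetic_config()] used when no input files are
#'   given.
#' @param degrees Course degrees to fit, subset of 1:3.
#' @param outcomes Outcome labels to model.
#' @param windows Scenario windows, subset of `c(24, 18, 12, 6)`.
#' @param n_bootstrap Bootstrap iterations for the Step-3 CIs (0 skips
#'   the bootstrap).
#' @param seed Master seed.
#' @param output_dir Directory for result files (created if needed).
#' @param use_abs_effects Passed through to the outcome models.
#' @param verbose Print stage-level progress.
#' @return A `run_config` list.
#' @export
run_config <- function(sbp_csv = NULL, covariate_csv = NULL,
                       synthetic = NULL, degrees = 1:3,
                       outcomes = outcome_names(),
                       windows = c(24, 18, 12, 6), n_bootstrap = 0,
                       seed = 1L, output_dir = "sbpcourse-results",
                       use_abs_effects = FALSE, verbose = TRUE) {
  if (!all(degrees %in% 1:3)) stop_sbp("degrees must be a subset of 1:3")
  if (!all(windows %in% c(24, 18, 12, 6)))
    stop_sbp("windows must be a subset of {24, 18, 12, 6}")
  outcomes <- match.arg(outcomes, outcome_names(), several.ok = TRUE)
  if (xor(is.null(sbp_csv), is.null(covariate_csv)))
    stop_sbp("supply both sbp_csv and covariate_csv, or neither")
  if (!is.null(sbp_csv)) {
    for (f in c(sbp_csv, covariate_csv))
      if (!file.exists(f)) stop_sbp("input file does not exist: %s", f)
  }
  structure(list(sbp_csv = sbp_csv, covariate_csv = covariate_csv,
                 synthetic = synthetic, degrees = as.integer(degrees),
                 outcomes = outcomes, windows = as.numeric(windows),
                 n_bootstrap = as.integer(n_bootstrap),
                 seed = as.integer(seed), output_dir = output_dir,
                 use_abs_effects = isTRUE(use_abs_effects),
                 verbose = isTRUE(verbose)),
            class = "run_config")
}

#' Run the full three-step pipeline
#'
#' Loads (or simulates) the cohort, applies the 24 h / 10-measurement
#' inclusion filter once, and then, for every requested
#' (outcome, degree): fits the reference course on the favourable
#' subgroup, projects EBLUP deviations for all included patients, fits
#' the logistic outcome model (with bootstrap CIs when requested) and
#' evaluates the scenario AUC grid over the requested windows. Every
#' artifact is written under `output_dir` and indexed in a JSON manifest
#' together with seeds and patient counts at every stage. A failing
#' stage is recorded in the manifest and downstream cells of that
#' (outcome, degree) are skipped; the run continues.
#'
#' @param config A [run_config()].
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(fmt, ...) if (config$verbose) message(sprintf(fmt, ...))

  if (!is.null(config$sbp_csv)) {
    cohort <- read_cohort(config$sbp_csv, config$covariate_csv)
    src <- list(type = "csv", sbp_csv = config$sbp_csv,
                covariate_csv = config$covariate_csv)
  } else {
    syn <- config$synthetic %||% synthetic_config(seed = config$seed)
    cohort <- generate_cohort(syn)
    write_cohort(cohort, file.path(config$output_dir, "sbp.csv"),
                 file.path(config$output_dir, "covariates.csv"))
    src <- list(type = "synthetic", n_patients = syn$n_patients,
                seed = syn$seed)
  }
  say("cohort: %d patients registered", length(cohort))

  flt <- window_filter(24)
  sel <- apply_inclusion_filter(cohort, flt)
  included <- sel$included
  say("inclusion filter (>= %d measurements in 24 h): %d included, %d excluded",
      flt$min_measurements, length(included), sel$n_excluded)

  manifest <- list(
    package_version = as.character(utils::packageVersion("sbpcourse")),
    seed = config$seed, source = src,
    n_registered = length(cohort), n_included = length(included),
    n_excluded = sel$n_excluded,
    proportions = setNames(lapply(config$outcomes, function(o)
      cohort_proportions(cohort, o)), config$outcomes),
    models = list(), failures = list())

  for (outc in config$outcomes) {
    for (deg in config$degrees) {
      key <- sprintf("%s_degree%d", outc, deg)
      say("model %s", key)
      entry <- tryCatch({
        spec <- course_spec(deg, outc)
        fav <- favourable_subcohort(included, outc)
        course <- fit_reference_course(fav, spec)
        write_course_json(course, file.path(
          config$output_dir, sprintf("course_%s.json", key)))
        eff <- eblup_table(included, course, 24)
        write.csv(eff, file.path(config$output_dir,
                                 sprintf("effects_%s.csv", key)),
                  row.names = FALSE)
        covs <- cohort_table(included)
        if (config$n_bootstrap > 0) {
          bs <- bootstrap_pipeline(included, spec,
                                   n_iterations = config$n_bootstrap,
                                   seed = derive_seed(config$seed, deg,
                                                      stream = 4L),
                                   use_abs_effects = config$use_abs_effects)
          fit <- bs$fit
          n_failed <- bs$n_failed_iterations
        } else {
          fit <- fit_outcome_model(eff, covs, outc,
                                   config$use_abs_effects)
          n_failed <- NA_integer_
        }
        write.csv(fit$coefficients,
                  file.path(config$output_dir,
                            sprintf("outcome_model_%s.csv", key)),
                  row.names = FALSE)
        grid <- run_scenarios(included, course, config$windows,
                              config$use_abs_effects)
        write.csv(grid, file.path(config$output_dir,
                                  sprintf("scenarios_%s.csv", key)),
                  row.names = FALSE)
        list(outcome = outc, degree = deg,
             n_favourable = length(fav), n_model = fit$n_used,
             bootstrap_iterations = config$n_bootstrap,
             bootstrap_failures = n_failed,
             scenario_auc = setNames(as.list(grid$auc),
                                     paste0("h", grid$window_hours)))
      }, error = function(e) {
        manifest$failures[[key]] <<- conditionMessage(e)
        NULL
      })
      if (!is.null(entry)) manifest$models[[key]] <- entry
    }
  }

  jsonlite::write_json(manifest,
                       file.path(config$output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(manifest)
}
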