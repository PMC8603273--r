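# sbpcourse

Systolic blood pressure (SBP) after endovascular thrombectomy (EVT) for
large-artery-occlusion stroke is dynamic, and most summary parameters
(peak SBP, variability, 24-h mean) are only known once the critical first
day is over. `sbpcourse` implements an individualised alternative: model
the *SBP course* of patients who went on to do well as a polynomial
mixed-effects "reference course", quantify how far any patient — favourable
or not — deviates from it, and use that deviation as an early predictor of
outcome. The package is aimed at stroke epidemiologists and biostatisticians
working with irregular post-EVT blood-pressure monitoring data.

## The model

**Step 1 — reference course.** On the favourable-outcome subcohort, fit a
linear mixed-effects model with a random effect on every coefficient
(degree *n* = 1, 2 or 3):

    SBP_ij = (a + u_i0) + (b + u_i1) t_ij + ... + e_ij,
    u_i ~ MVN(0, G),   e_ij ~ N(0, sigma_e^2)

`alpha = (a, b, c, d)` are the course's level (mm Hg), trend (mm Hg/h),
curvature and twist; `G` is the unstructured random-effects covariance
(diagonal constrained positive); `t` is hours since end of EVT, 0–24.
Estimation maximises the marginal likelihood, profiled over `alpha` and
`sigma_e^2`, by quasi-Newton over a log-diagonal Cholesky factor of
`G / sigma_e^2` (compiled in C++; ML default, REML optional).

**Step 2 — deviation.** For *every* patient (both outcome groups), the
empirical best linear unbiased predictor

    b_i = G Z_i' (Z_i G Z_i' + sigma_e^2 I)^{-1} (q_i - Z_i alpha)

shrinks the observed residual towards zero depending on the number of
measurements and the variance ratio; `Z_i` is the polynomial design at the
patient's own measurement times.

**Step 3 — prediction.** Logistic regression of the binary outcome on all
deviation components simultaneously plus age, sex, baseline NIHSS,
hypertension history and recanalisation success (mTICI 2b–3). Because
Steps 1–2 are treated as known, 95% CIs come from bootstrapping *all*
steps (default 1000 iterations). Predictive stability is probed by
recomputing EBLUPs from only the first 24/18/12/6 h of measurements
(minimum 10/8/6/3 measurements) against the unchanged course parameters
and reporting apparent ROC AUCs per cell.

No hospital dataset is bundled: a synthetic-cohort generator emulates the
monitoring protocol (21 scheduled + 8 optional measurements), the
random-coefficient SBP model, covariate marginals and logistic outcome
labels, so the full pipeline is testable end to end.

## Worked example

```r
library(sbpcourse)

# reported linear reference course for functional independence:
rc <- reported_course("functional_independence", degree = 1)
round(evaluate_course(rc, c(0, 24)))
#> [1] 130 123        # 130 mm Hg at EVT end, 123 mm Hg at 24 h

# end-to-end on a synthetic cohort
cohort   <- generate_cohort(synthetic_config(n_patients = 120, seed = 42))
included <- apply_inclusion_filter(cohort, window_filter(24))$included
fav      <- favourable_subcohort(included, "functional_independence")
course   <- fit_reference_course(fav, course_spec(1))
course
#> Reference SBP course (degree 1, favourable 'functional_independence')
#>   fixed effects: level = 127.6, trend = -0.3653
#>   residual variance: 65.29 mm Hg^2
#>   G diagonal: 76.24, 0.1758
#>   log-likelihood: -3576.178 (n = 47 patients)

eff <- eblup_table(included, course, 24)       # per-patient deviations
fit <- fit_outcome_model(eff, cohort_table(included),
                         "functional_independence")
compute_auc(fit$scores, fit$labels)
#> [1] 0.7644644

run_scenarios(included, course)[, c("window_hours", "auc", "n_included")]
#>   window_hours       auc n_included
#> 1           24 0.7644644        104
#> 2           18 0.7887271        104
#> 3           12 0.7749160        104
#> 4            6 0.7525196        104
```

The fitted level/trend sit near the generating course (130, −0.28 at a
47-patient reference subgroup); the apparent AUC moves by only a few
hundredths when EBLUPs use early measurements only — the stability
property the deviation predictor is designed for.

## Layout

- `R/`, `src/` — implementation (generator, course fit, EBLUP, outcome
  models, scenarios, IO/CLI, brute-force oracles)
- `vignettes/sbp-course-deviation.Rmd` — methods notes: model,
  assumptions, tuning parameters, what the generator does and does not
  emulate
- `inst/cli/sbpcourse.R` — command-line entry point
  (`simulate | fit | project | predict | run | validate`)
- `tests/testthat/` — unit, property and acceptance suites
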