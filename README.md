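# orthomediate

Cardiovascular dysautonomia and clinical disease burden in Parkinson
cohorts: tilt-test classification, cardiac MIBG metrics, composite
severity z-scores, and covariate-adjusted mediation analysis with
percentile-bootstrap inference.

## What it is for

In early Parkinson disease, reduced myocardial uptake of ^123^I-MIBG
(cardiac sympathetic denervation, summarized by the delayed
heart-to-mediastinum ratio H/M) and orthostatic hypotension (OH) are both
markers of worse outcomes — and denervation contributes to OH. For anyone
analyzing such a cohort, the natural question is a mediation one: letting
*a* be the delayed H/M ratio, *b* the orthostatic systolic or diastolic
BP drop (ΔBPmin), and *c* a composite severity score, does *a* affect *c*
directly, or through *b*? The package implements the full quantitative
chain:

* **`tilt_profiles()`** — head-up tilt-test series → supine averages,
  ΔBPmin / ΔBPmax per channel, and supine hypertension (SH, supine BP ≥
  140/90), orthostatic hypotension (drop ≥ 20/10 mmHg within 5 min, or
  ≥ 30/15 under SH) and orthostatic hypertension (rise ≥ 20/10, or tilted
  BP ≥ 140/90 without SH) flags.
* **`mibg_metrics()`** — H/M ratios from ROI counts or given directly,
  washout rate `100·(early − delayed)/early`, and the normal/abnormal
  classification (delayed H/M < 1.78 by default).
* **`add_composites()`** — motor, sleep, autonomic and global composites
  as means of cohort z-scores across standard rating scales.
* **`compare_groups()`**, `pooled_t()`, `welch_t()`, `mann_whitney_u()`,
  `fisher_exact()` — the descriptive two-group table.
* **`mediate()`** — the core model. Two linear regressions,
  `b ~ a + covariates` and `c ~ a + b + covariates`, fitted on
  mean-centered predictors by least squares with maximum-likelihood
  standard errors; effects decomposed as **indirect** = αβ_b,
  **direct** = τ′, **total** = τ′ + αβ_b; Sobel SE and normal z/p for
  each effect; percentile-bootstrap confidence intervals from case
  resampling; completely standardized betas. Returns a classed object
  with `print`, `summary`, `coef`, `confint` and `plot` methods.
* **`simulate_cohort()`** — a seeded generator producing raw tilt series,
  MIBG values, demographics and questionnaire totals under a configurable
  structural model, so every stage is testable without patient data.
* **`run_pipeline()`** — chains everything and writes a report bundle.

## Worked example

```r
library(orthomediate)

sim <- simulate_cohort(sim_params(), seed = 42)       # 227 synthetic patients
bundle <- run_pipeline(sim$cohort, sim$tilt, n_boot = 1000, seed = 42)
bundle$mediation[["global_z~delayed_hm~delta_sbp_min"]]
```

```
Mediation analysis (n = 227)
  predictor (a): delayed_hm   mediator (b): delta_sbp_min   outcome (c): global_z
  covariates: age, duration (mean-centered)
  percentile bootstrap CIs, 1000 resamples, level 0.95

                      path estimate    se  ci_low ci_high   beta      z     p
indirect       a -> b -> c   -0.074 0.044  -0.158  -0.007 -0.044 -1.698 0.089
a_to_b              a -> b  -12.671 2.162 -16.925  -8.466 -0.363 -5.861 0.000
b_to_c              b -> c    0.006 0.003   0.001   0.012  0.122  1.775 0.076
direct              a -> c   -0.278 0.115  -0.484  -0.079 -0.166 -2.413 0.016
total    indirect + direct   -0.352 0.108  -0.547  -0.167 -0.210 -3.257 0.001
```

Reading it: each H/M unit of preserved uptake is associated with a
12.7 mmHg smaller orthostatic systolic drop (`a_to_b`; denervated
patients drop more), and with 0.35 z less global burden in total —
almost all of it direct (`a -> c`), not routed through the BP drop: the
near-null `b -> c` path keeps the indirect effect small. The group
comparison table tells the same story descriptively:

```r
bundle$table1[bundle$table1$variable %in%
                c("delta_sbp_min", "washout_rate", "global_z", "oh"), ]
```

```
        variable mibg_class=normal mibg_class=abnormal   test    statistic  df            p
5  delta_sbp_min          5 (12.6)         13.9 (12.8) pooled -4.756657036 225 3.516876e-06
9   washout_rate          -4 (6.3)           3.4 (9.5) pooled -5.756048248 225 2.801070e-08
10      global_z        -0.2 (0.6)           0.1 (0.7) pooled -2.612950061 225 9.581591e-03
15            oh         10 (15.4)           56 (34.6) fisher  0.001727411  NA 3.663121e-03
```

Continuous rows show mean (SD) per MIBG group; the `oh` row shows n (%)
with Fisher's exact p. See `vignette("orthomediate-methods")` for the
model details, generator calibration and validation strategy.

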