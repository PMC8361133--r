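---
title: "Models and methods in orthomediate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in orthomediate}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orthomediate)
```

# The scientific question

Two cardiovascular biomarkers travel together in Parkinson disease (PD).
Cardiac sympathetic denervation — reduced myocardial uptake of
^123^I-MIBG, summarized by the delayed heart-to-mediastinum (H/M) ratio —
is associated both with orthostatic hypotension (OH) and with worse motor
and nonmotor severity. That raises a mediation question: does denervation
worsen clinical burden *through* orthostatic blood-pressure (BP)
instability, or directly? `orthomediate` implements every quantitative
step needed to ask that question of a cohort: tilt-test classification,
MIBG metrics, composite severity z-scores, descriptive group statistics,
and a covariate-adjusted simple mediation engine with percentile-bootstrap
inference — plus a synthetic-cohort generator so the whole pipeline can be
validated without patient data.

# Tilt-test classification

The protocol measures BP every 5 minutes over 20 supine minutes, then at
0, 3, 5, 10, 15 and 20 minutes after head-up tilt to 60 degrees.
`tilt_profiles()` operationalizes:

* **Supine average.** Mean of the 5-, 10-, 15- and 20-minute supine
  SBP/DBP; the 0-minute reading is discarded (taken before full rest).
  Missing any of the four required readings is a hard error naming the
  time point.
* **Supine hypertension (SH).** Average supine BP ≥ 140 mmHg systolic
  and/or ≥ 90 diastolic, inclusive.
* **ΔBPmin.** Supine average minus the *lowest* tilted value at 3 or 5
  minutes; positive Δ = drop on standing. SBP and DBP minima are selected
  independently per channel (possibly at different time points) — the
  threshold notation "20/10" treats the channels separately, and nothing
  in the definitions binds them to one time point.
* **OH.** ΔSBPmin ≥ 20 and/or ΔDBPmin ≥ 10 mmHg; under SH the cutoffs
  rise to 30/15. The "within 5 minutes" constraint is structural: only the
  3/5-minute pool feeds ΔBPmin.
* **ΔBPmax and OHT.** Supine average minus the *highest* tilted value over
  3–20 minutes (the tilted 0-minute reading is never pooled). A rise of
  20/10 (ΔBPmax ≤ −20 systolic and/or ≤ −10 diastolic) defines
  orthostatic hypertension; patients without SH are also OHT when their
  highest tilted BP reaches 140/90. For the 140/90 arm we read "and/or"
  disjunctively (SBP ≥ 140 *or* DBP ≥ 90), consistent with every other
  threshold pair in the scheme.

All thresholds are inclusive as printed. OH and OHT are not exclusive: a
patient can drop early and overshoot late. Because the 3/5-minute pool is
a subset of the 3–20-minute pool, ΔBPmin ≥ ΔBPmax always holds; the test
suite asserts this over randomized series. Tilted pools operate on the
available time points (with a warning when incomplete); BP values are
accepted as integers or decimals, and no rounding happens inside
classification.

# MIBG metrics

`hm_ratio()` divides heart by mediastinal uptake from the regions of
interest; `washout_rate()` is `100 * (early − delayed) / early`, negative
when delayed uptake exceeds early uptake (typical of preserved
sympathetic tone); `classify_mibg()` marks a delayed H/M strictly below
the reference limit as abnormal. The limit defaults to 1.78 but is a
parameter because it is site- and camera-calibrated. No decay correction
is applied to the washout rate: none is part of the definition used here.
The cohort interface accepts either the H/M ratios directly (the usual
granularity of reported data) or raw ROI counts.

# Composite severity scores

Each questionnaire total (UPDRS II/III, NMSS, MADRS, ESS, PDSS-2, RBDSQ,
SCOPA-AUT without its sexual-dysfunction items, OHQ parts I and II summed
separately) is standardized to a cohort z-score with the sample (n−1) SD.
Composites are unweighted means of component z-scores: motor (UPDRS II,
III), sleep (ESS, PDSS-2, RBDSQ), autonomic (OHQ I, OHQ II, SCOPA-AUT)
and global. Higher z = worse severity.

Design choices the definitions leave open, and how we resolved them:

* "Scaled z-scores" is read as plain cohort standardization; no 0–100
  pre-scaling is applied (none is defined anywhere).
* The global composite defaults to the ten instruments above. UPDRS I,
  H&Y, MMSE and CDR are excluded — they appear only descriptively, never
  in a composite. Membership is configurable (`global_set`).
* OHQ contributes two z-columns because its parts are summed separately;
  `ohq_mode = "combined"` collapses them to one z of the sum.
* Whether standardization uses the population (n) or sample (n−1) SD is
  unstated; n−1 is adopted. The choice cancels out of any mean-of-z
  composite comparison.
* Missing data: a column is standardized on its observed values; a
  patient's composite is the mean of their observed component z-scores
  when at least half are present, else missing. Only the SCOPA-AUT
  sexual-section omission is prescribed by the source definitions; the
  half-rule mirrors common practice.

Every composite has cohort mean 0 by construction and SD ≤ 1 (averaging
shrinks variance unless components correlate perfectly); composites are
invariant to affine rescaling of any raw instrument.

# The mediation model

With predictor *a* (delayed H/M ratio; alternatively the early ratio or
the washout rate), mediator *b* (ΔSBPmin or ΔDBPmin), outcome *c* (a
composite score) and covariates age and disease duration, `mediate()`
fits two linear models on listwise-complete cases:

$$ b = i_1 + \alpha\,a + \gamma_1' x + \varepsilon_1 $$
$$ c = i_2 + \tau'\,a + \beta_b\,b + \gamma_2' x + \varepsilon_2 $$

and decomposes the association into **indirect** = αβ_b, **direct** = τ′,
and **total** = τ′ + αβ_b, which equals the coefficient of *a* in the
auxiliary regression of *c* on *a* and the covariates exactly (an
algebraic identity of least squares; the suite asserts it at machine
precision). Predictor, mediator and covariates are mean-centered before
fitting as a multicollinearity guard; centering moves only intercepts, and
the tests confirm estimates, betas and bootstrap CIs are identical with
and without it.

Numerical and inferential choices:

* **Standard errors.** Coefficient SEs use the maximum-likelihood
  residual variance (RSS/n), the convention of path-analysis software;
  `var_type = "unbiased"` switches to RSS/(n−p) and affects SEs only.
  The indirect effect's SE is the first-order Sobel delta-method value
  $\sqrt{\beta_b^2\,se_\alpha^2 + \alpha^2\,se_\beta^2}$; the exact
  formula behind reported indirect SEs is rarely stated in applied work,
  and the bootstrap — not this SE — is the inferential authority here.
  z = estimate/SE with two-sided normal p-values.
* **Percentile bootstrap.** Cases (rows) are resampled jointly with
  replacement, preserving covariate association; all five effects are
  re-estimated per resample and the CI bounds are the empirical 2.5th and
  97.5th percentiles. A single integer seed makes the resample stream
  deterministic; a degenerate (collinear) resample is redrawn up to a cap
  and the redraws are reported. Stratification is not used.
* **Betas.** Completely standardized effects: β(a→b) = α·SD(a)/SD(b),
  β(b→c) = β_b·SD(b)/SD(c), β(direct) = τ′·SD(a)/SD(c), with the
  product/sum identities defining the indirect and total betas.
  Covariates are centered but not standardized, and no beta is reported
  for them.
* **Degenerate inputs.** Collinear designs fail with the offending
  columns named; zero-variance variables and cohorts with fewer than 10
  complete cases are hard errors.

`ols_ml()` is checked against a normal-equations oracle and against
`lm()`; the two-sample and exact tests used in the descriptive table
(`pooled_t()`, `welch_t()`, `mann_whitney_u()`, `fisher_exact()`) are
checked against `stats` and against brute-force enumeration. The pooled t
accepts `(n, mean, sd)` summaries so published summary statistics can be
re-tested directly. Fisher's two-sided p follows the
probability-at-most-observed rule (the common software convention;
two-sided Fisher conventions differ, so this is stated explicitly), with
a 1e-12 relative tolerance absorbing floating-point ties. The
Mann-Whitney U uses midranks; for n₁+n₂ ≤ 12 the p-value is an exact
enumeration over group assignments (valid under ties, where the classical
exact distribution is not), otherwise a tie-corrected normal
approximation with optional continuity correction.

# The synthetic cohort generator

`simulate_cohort()` emulates the statistical shape the analysis assumes,
with defaults fixed at the study conditions: n = 227; delayed H/M a
two-component mixture (abnormal fraction 0.696, components 1.34 (0.18)
and 2.04 (0.16)); path coefficients α = −11.665 mmHg per H/M unit
(systolic; −5.270 diastolic), β_b = 0.002 z per mmHg (near-null, as
estimated), τ′ = −0.441 z per H/M unit; age 69.6 (9.2) years and duration
1.1 (1.0, ≥ 0.1) years entering both equations so covariate adjustment is
exercised non-trivially.

Values the printed record does not determine were fixed once at
realistic levels and documented here:

* Residual SDs: σ_b = 12.5 mmHg (systolic) and 7.4 (diastolic) reproduce
  the printed marginal ΔBPmin SDs (13.3 / 7.8) after accounting for the
  H/M path; σ_burden = 0.65 puts latent burden on the global-composite z
  scale (marginal SD ≈ 0.7).
* Early H/M = delayed + a group offset (+0.07 abnormal, −0.08 normal,
  noise SD 0.13), reproducing washout-rate means near +5% and −4.9% with
  SDs near 7.
* ΔBPmax = ΔBPmin − gap with a non-negative truncated-normal gap (means
  9.7 / 7.1 mmHg), so the subset-pool ordering holds by construction;
  systolic/diastolic residuals share a latent orthostatic factor
  (r = 0.6), and supine SBP/DBP are drawn with correlation 0.6 to keep
  pulse pressure physiologic.
* Questionnaire totals are integer, range-clamped affine functions of
  standardized latent burden with loading 0.6 (MMSE loads negatively).

BP targets are rounded to integer mmHg and realized as raw series by
`construct_tilt_series()`, built so that `tilt_profiles()` reproduces the
targets *exactly* (the round-trip is asserted for 10,000 patients). Group
membership in analyses is always re-derived from the sampled delayed H/M
via the cutoff — the mixture components overlap, and classification is the
operational truth. Rare BP-target combinations that would imply
non-physiologic series (tilted DBP crossing SBP) are repaired by capping
the systolic drop; the repair count is attached to the cohort and stays
well below 1% under default parameters.

What the generator does **not** emulate: the true joint distribution of
ΔBP and H/M (unknowable from printed summaries — only the stated marginal
and path structure is promised); beat-to-beat hemodynamics; longitudinal
progression; diagnostic misclassification. Two visible consequences:
supine-hypertension prevalence comes out near 18–20% rather than the
reported 8.8%, because a normal supine-BP marginal with the printed mean
and SD puts more mass above 140 mmHg than the real, right-skewed cohort
did; and orthostatic-hypertension prevalence runs somewhat above the
reported 26.4% for the same reason. Passing tests therefore demonstrate
correctness of the *computations* under a plausible data-generating
process, not distributional fidelity of every prevalence to the original
cohort.

# Validation strategy and problem sizes

The test suite works oracle-first: hand-computed examples for every
classification rule; brute-force enumeration oracles for Fisher and
Mann-Whitney; normal equations for least squares; spreadsheet-style
recomputation for composites; and published worked arithmetic (count
percentages, a pooled t from printed summaries, standardized-coefficient
identities) reproduced at printed precision. Stochastic properties use
fixed seeds and sizes chosen to keep Monte-Carlo error far from the
asserted bounds: mixture calibration at n = 10,000 (3 MC-SE bands),
parameter recovery as the mean over ten n = 5,000 replicate cohorts
(recovery is a bias property; a single replicate's MC spread is
comparable to the 5% band being asserted), and percentile-bootstrap
coverage of the indirect effect over 500 replicate cohorts of n = 200
with 1,000 resamples each, asserted within 92–98% against the known true
indirect effect in a setting where both component paths are clearly
identified (a near-null product makes percentile intervals conservative
and would test the wrong thing).

# Limitations

The engine fits one mediator at a time (fit systolic and diastolic models
separately, as the source analysis did); there is no moderated mediation,
no latent-variable measurement model, and missing data are handled by
listwise deletion, not FIML. Normal-theory p-values accompany the ML SEs
for compatibility with reported tables, but for the indirect effect —
whose sampling distribution is a product and non-normal in small samples
— the percentile bootstrap CI is the inference to trust.
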