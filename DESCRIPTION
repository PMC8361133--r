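Package: orthomediate
Title: Orthostatic Blood-Pressure Classification, Cardiac MIBG Metrics, and
    Mediation Analysis for Early Parkinson Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying cardiovascular dysautonomia in Parkinson
    disease cohorts and relating it to clinical disease burden. Classifies
    supine hypertension, orthostatic hypotension and orthostatic hypertension
    from head-up tilt-test blood-pressure series; computes heart-to-mediastinum
    uptake ratios and the washout rate from cardiac MIBG scintigraphy; builds
    motor, sleep, autonomic and global composite z-scores from standard rating
    scales; and fits covariate-adjusted simple mediation models with
    maximum-likelihood standard errors, Sobel tests and percentile-bootstrap
    confidence intervals. A seeded synthetic-cohort generator reproduces the
    joint structure these analyses assume, so the full pipeline can be
    exercised and validated without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports: graphics, jsonlite, stats, utils
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
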