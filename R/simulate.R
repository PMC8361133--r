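# Seeded synthetic-cohort generator.  Structural model:
#
#   group        ~ Bernoulli(p_abnormal)
#   delayed H/M  ~ N(mu_g, sd_g) per group (two-component mixture)
#   early H/M    = delayed + offset_g + noise
#   dSBPmin      = b0 + theta_ab_sbp (hm - E hm) + covariate terms + noise
#   dDBPmin      analogous, noise correlated with the SBP noise (shared
#                latent orthostatic factor)
#   dBPmax       = dBPmin - gap, gap >= 0 (the 3-20 min pool contains the
#                3/5 min pool, so the max-based delta can never exceed the
#                min-based one)
#   burden L     = theta_ac (hm - E hm) + theta_bc (dSBPmin - E) +
#                covariate terms + noise   (global-composite z scale)
#   scale total  = clamped, rounded  mean + sd (lambda z(L) + noise)
#
# BP targets are rounded to integer mmHg and realized as raw tilt series by
# construct_tilt_series(), whose output round-trips exactly through
# tilt_profiles().  Group membership in analyses is always re-derived from
# the sampled delayed H/M via the cutoff, never taken from the mixture
# component.

#' Parameters of the synthetic-cohort generator
#'
#' Defaults describe an early, drug-naive Parkinson cohort: a two-component
#' delayed H/M mixture (abnormal fraction 0.696; components 1.34 (0.18) and
#' 2.04 (0.16)), a negative H/M to orthostatic-drop path
#' (`theta_ab_sbp` = -11.665 mmHg per H/M unit, `theta_ab_dbp` = -5.270), a
#' near-null drop-to-burden path (`theta_bc` = 0.002 z per mmHg) and a
#' negative direct H/M-to-burden path (`theta_ac` = -0.441 z per H/M unit),
#' with age 69.6 (9.2) years and disease duration 1.1 (1.0) years
#' (truncated at 0.1) entering both the mediator and burden equations.
#'
#' @param n_patients Cohort size (default 227).
#' @param p_abnormal Mixture weight of the low-uptake (denervated) component.
#' @param hm_abnormal,hm_normal `c(mean, sd)` of delayed H/M per component.
#' @param early_offset_abnormal,early_offset_normal Mean difference early
#'   minus delayed H/M per component (abnormal scans wash out, so early
#'   exceeds delayed; preserved scans continue accumulating).
#' @param early_noise_sd SD of the early-H/M measurement noise.
#' @param theta_ab_sbp,theta_ab_dbp Path a->b: mmHg of orthostatic drop per
#'   H/M unit (systolic/diastolic mediators).
#' @param theta_bc Path b->c: burden z per mmHg of systolic drop.
#' @param theta_ac Direct path a->c: burden z per H/M unit.
#' @param b0_sbp,b0_dbp Mean orthostatic drops (mmHg) at the average H/M.
#' @param sigma_b_sbp,sigma_b_dbp Residual SDs of the drop equations; with
#'   the H/M path they reproduce marginal drop SDs near 13.3/7.8 mmHg.
#' @param delta_corr Correlation of the systolic and diastolic drop residuals
#'   (shared latent orthostatic factor).
#' @param gap_sbp,gap_dbp `c(mean, sd)` of the non-negative min-to-max gap
#'   per channel (mmHg).
#' @param supine_sbp,supine_dbp `c(mean, sd)` of the average supine BP.
#' @param supine_corr Correlation of the supine systolic and diastolic
#'   draws (keeps pulse pressure physiologic).
#' @param age,duration `c(mean, sd)` of age (years) and disease duration
#'   (years; truncated at 0.1).
#' @param beta_age_b,beta_dur_b Covariate effects on the systolic drop
#'   (mmHg per year); the diastolic equation uses half these values.
#' @param beta_age_c,beta_dur_c Covariate effects on latent burden (z per
#'   year).
#' @param sigma_burden Residual SD of latent burden (global-composite z
#'   scale).
#' @param lambda Loading of each questionnaire total on standardized burden.
#' @param p_female Proportion of female patients.
#' @return A classed list of parameters (`"sim_params"`).
#' @export
sim_params <- function(n_patients = 227,
                       p_abnormal = 0.696,
                       hm_abnormal = c(mean = 1.34, sd = 0.18),
                       hm_normal = c(mean = 2.04, sd = 0.16),
                       early_offset_abnormal = 0.07,
                       early_offset_normal = -0.08,
                       early_noise_sd = 0.13,
                       theta_ab_sbp = -11.665,
                       theta_ab_dbp = -5.270,
                       theta_bc = 0.002,
                       theta_ac = -0.441,
                       b0_sbp = 10.6,
                       b0_dbp = 2.8,
                       sigma_b_sbp = 12.5,
                       sigma_b_dbp = 7.4,
                       delta_corr = 0.6,
                       gap_sbp = c(mean = 9.7, sd = 6.0),
                       gap_dbp = c(mean = 7.1, sd = 5.0),
                       supine_sbp = c(mean = 124.1, sd = 16.5),
                       supine_dbp = c(mean = 71.0, sd = 9.1),
                       supine_corr = 0.6,
                       age = c(mean = 69.6, sd = 9.2),
                       duration = c(mean = 1.1, sd = 1.0),
                       beta_age_b = 0.15,
                       beta_dur_b = 1.0,
                       beta_age_c = 0.01,
                       beta_dur_c = 0.10,
                       sigma_burden = 0.65,
                       lambda = 0.6,
                       p_female = 0.463) {
  p <- as.list(environment())
  if (p$n_patients < 2) stop("n_patients must be at least 2", call. = FALSE)
  for (pr in c("p_abnormal", "p_female")) {
    if (p[[pr]] < 0 || p[[pr]] > 1) {
      stop(pr, " must be in [0, 1]", call. = FALSE)
    }
  }
  for (sdname in c("early_noise_sd", "sigma_b_sbp", "sigma_b_dbp",
                   "sigma_burden")) {
    if (p[[sdname]] <= 0) stop(sdname, " must be positive", call. = FALSE)
  }
  for (pair in c("hm_abnormal", "hm_normal", "gap_sbp", "gap_dbp",
                 "supine_sbp", "supine_dbp", "age", "duration")) {
    if (length(p[[pair]]) != 2 || p[[pair]][2] <= 0) {
      stop(pair, " must be c(mean, sd) with sd > 0", call. = FALSE)
    }
  }
  if (abs(p$delta_corr) > 1) stop("delta_corr must be in [-1, 1]", call. = FALSE)
  if (abs(p$supine_corr) > 1) stop("supine_corr must be in [-1, 1]", call. = FALSE)
  if (abs(p$lambda) > 1) stop("lambda must be in [-1, 1]", call. = FALSE)
  structure(p, class = "sim_params")
}

#' @export
print.sim_params <- function(x, ...) {
  cat("Synthetic-cohort parameters:\n")
  for (nm in names(x)) {
    v <- x[[nm]]
    cat("  ", format(nm, width = 22), paste(format(unname(v)), collapse = " / "),
        "\n", sep = "")
  }
  invisible(x)
}

# Instrument catalogue: plausible cohort mean/SD of each total and the
# published score range used for clamping.
instrument_catalogue <- function() {
  data.frame(
    name = c("updrs_i", "updrs_ii", "updrs_iii", "nmss", "madrs", "ess",
             "pdss2", "rbdsq", "scopa_aut", "ohq_i", "ohq_ii", "mmse"),
    mean = c(1.6, 6.1, 15.8, 24.0, 5.0, 2.9, 7.4, 3.2, 8.1, 4.5, 3.2, 26.8),
    sd = c(1.4, 4.1, 8.6, 20.0, 5.5, 2.7, 6.8, 2.6, 6.7, 7.5, 5.5, 3.0),
    min = 0,
    max = c(16, 52, 108, 360, 60, 24, 60, 13, 69, 60, 40, 30),
    # mmse loads negatively: higher cognition = less burden
    loading_sign = c(1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, -1),
    stringsAsFactors = FALSE
  )
}

rnorm_trunc <- function(n, mean, sd, lower) {
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x < lower)
  for (i in bad) {
    repeat {
      xi <- stats::rnorm(1, mean, sd)
      if (xi >= lower) break
    }
    x[i] <- xi
  }
  x
}

#' Build a raw tilt-test series realizing target deltas exactly
#'
#' Inverse of the tilt classifier: emits a long-format series whose
#' [tilt_profiles()] output reproduces the integer supine-average and delta
#' targets exactly. Four supine readings (5-20 min) average exactly to the
#' supine target; the 3-min tilted reading carries the pool minimum
#' (`supine - delta_min`), the 15-min reading the pool maximum
#' (`supine - delta_max`), and the remaining tilted readings lie between the
#' two. All arguments are vectorized over patients.
#'
#' @param patient_id Identifier vector.
#' @param supine_sbp,supine_dbp Integer supine-average targets (mmHg).
#' @param dmin_sbp,dmin_dbp Integer \eqn{\Delta}BPmin targets (mmHg).
#' @param dmax_sbp,dmax_dbp Integer \eqn{\Delta}BPmax targets (mmHg); must
#'   not exceed the min-based targets (subset-pool ordering).
#' @return Long data frame with columns `patient_id`, `phase`, `time_min`,
#'   `sbp`, `dbp` (11 rows per patient: supine 0-20, tilted 0-20 min).
#' @export
construct_tilt_series <- function(patient_id, supine_sbp, supine_dbp,
                                  dmin_sbp, dmin_dbp, dmax_sbp, dmax_dbp) {
  n <- length(patient_id)
  args <- list(supine_sbp, supine_dbp, dmin_sbp, dmin_dbp, dmax_sbp, dmax_dbp)
  if (any(lengths(args) != n)) stop("all arguments must have equal length",
                                    call. = FALSE)
  if (any(unlist(args) != round(unlist(args)))) {
    stop("targets must be integer mmHg", call. = FALSE)
  }
  if (any(dmin_sbp < dmax_sbp) || any(dmin_dbp < dmax_dbp)) {
    stop("infeasible targets: delta_min must be >= delta_max per channel ",
         "(the 3/5-min pool is a subset of the 3-20-min pool)", call. = FALSE)
  }
  lo_sbp <- supine_sbp - dmin_sbp
  hi_sbp <- supine_sbp - dmax_sbp
  lo_dbp <- supine_dbp - dmin_dbp
  hi_dbp <- supine_dbp - dmax_dbp
  # lowest tilted SBP strictly above highest tilted DBP guarantees
  # 0 < dbp < sbp at every tilted time point
  if (any(lo_sbp <= hi_dbp) || any(supine_dbp >= supine_sbp) ||
      any(lo_dbp <= 0) || any(hi_sbp >= 300)) {
    stop("infeasible targets: tilted series would violate 0 < dbp < sbp < 300",
         call. = FALSE)
  }
  mid_sbp <- round((lo_sbp + hi_sbp) / 2)
  mid_dbp <- round((lo_dbp + hi_dbp) / 2)
  sup_t <- c(0, 5, 10, 15, 20)
  # 5-20 min supine values sum to exactly 4 * target
  sup_sbp <- cbind(supine_sbp, supine_sbp + 1, supine_sbp - 1,
                   supine_sbp, supine_sbp)
  sup_dbp <- cbind(supine_dbp, supine_dbp + 1, supine_dbp - 1,
                   supine_dbp, supine_dbp)
  tilt_t <- c(0, 3, 5, 10, 15, 20)
  tilt_sbp <- cbind(supine_sbp, lo_sbp, mid_sbp, mid_sbp, hi_sbp, mid_sbp)
  tilt_dbp <- cbind(supine_dbp, lo_dbp, mid_dbp, mid_dbp, hi_dbp, mid_dbp)
  data.frame(
    patient_id = rep(patient_id, each = length(sup_t) + length(tilt_t)),
    phase = rep(rep(c("supine", "tilt"), c(length(sup_t), length(tilt_t))), n),
    time_min = rep(c(sup_t, tilt_t), n),
    sbp = as.vector(rbind(t(sup_sbp), t(tilt_sbp))),
    dbp = as.vector(rbind(t(sup_dbp), t(tilt_dbp))),
    stringsAsFactors = FALSE
  )
}

#' Generate a seeded synthetic cohort
#'
#' Samples demographics, MIBG uptake, orthostatic BP targets, latent disease
#' burden and questionnaire totals under the structural model described in
#' [sim_params()], and realizes the BP targets as raw tilt-test series via
#' [construct_tilt_series()]. The classifier-derived deltas round-trip
#' exactly to the generated targets. Identical `seed` gives identical
#' output.
#'
#' @param params A [sim_params()] object.
#' @param seed Integer seed (`NULL` uses the current RNG state).
#' @return List with `cohort` (one row per patient: demographics, H/M
#'   ratios, `latent_burden`, questionnaire totals and the BP targets) and
#'   `tilt` (the long-format raw tilt series). The number of feasibility
#'   repairs of BP targets is attached as `attr(, "n_bp_repairs")` on
#'   `cohort`.
#' @export
#' @examples
#' sim <- simulate_cohort(sim_params(n_patients = 50), seed = 1)
#' head(sim$cohort)
simulate_cohort <- function(params = sim_params(), seed = NULL) {
  if (!inherits(params, "sim_params")) {
    stop("params must come from sim_params()", call. = FALSE)
  }
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    }
    set.seed(seed)
  }
  n <- params$n_patients
  id <- sprintf("P%04d", seq_len(n))
  age <- stats::rnorm(n, params$age[1], params$age[2])
  duration <- rnorm_trunc(n, params$duration[1], params$duration[2], 0.1)
  sex <- ifelse(stats::runif(n) < params$p_female, "F", "M")

  abn <- stats::runif(n) < params$p_abnormal
  delayed_hm <- ifelse(abn,
    stats::rnorm(n, params$hm_abnormal[1], params$hm_abnormal[2]),
    stats::rnorm(n, params$hm_normal[1], params$hm_normal[2]))
  delayed_hm <- pmax(delayed_hm, 0.5)
  early_hm <- delayed_hm +
    ifelse(abn, params$early_offset_abnormal, params$early_offset_normal) +
    stats::rnorm(n, 0, params$early_noise_sd)
  early_hm <- pmax(early_hm, 0.5)

  hm_mean <- params$p_abnormal * params$hm_abnormal[1] +
    (1 - params$p_abnormal) * params$hm_normal[1]
  hm_c <- delayed_hm - hm_mean
  age_c <- age - params$age[1]
  dur_c <- duration - params$duration[1]

  # correlated residuals of the two drop equations (shared latent factor)
  u <- stats::rnorm(n)
  lam <- sqrt(params$delta_corr)
  e_sbp <- lam * u + sqrt(1 - params$delta_corr) * stats::rnorm(n)
  e_dbp <- lam * u + sqrt(1 - params$delta_corr) * stats::rnorm(n)

  dmin_sbp_raw <- params$b0_sbp + params$theta_ab_sbp * hm_c +
    params$beta_age_b * age_c + params$beta_dur_b * dur_c +
    params$sigma_b_sbp * e_sbp
  dmin_dbp_raw <- params$b0_dbp + params$theta_ab_dbp * hm_c +
    params$beta_age_b / 2 * age_c + params$beta_dur_b / 2 * dur_c +
    params$sigma_b_dbp * e_dbp
  gap_s <- rnorm_trunc(n, params$gap_sbp[1], params$gap_sbp[2], 0)
  gap_d <- rnorm_trunc(n, params$gap_dbp[1], params$gap_dbp[2], 0)

  zs <- stats::rnorm(n)
  zd <- params$supine_corr * zs +
    sqrt(1 - params$supine_corr^2) * stats::rnorm(n)
  supine_sbp <- round(params$supine_sbp[1] + params$supine_sbp[2] * zs)
  supine_dbp <- round(params$supine_dbp[1] + params$supine_dbp[2] * zd)
  # keep the supine pulse pressure physiologic
  narrow <- supine_dbp > supine_sbp - 15
  supine_dbp[narrow] <- supine_sbp[narrow] - 15

  dmin_sbp <- round(dmin_sbp_raw)
  dmin_dbp <- round(dmin_dbp_raw)
  dmax_sbp <- round(dmin_sbp_raw - gap_s)
  dmax_dbp <- round(dmin_dbp_raw - gap_d)

  # feasibility repairs (rare): every tilted reading needs 0 < dbp < sbp
  repairs <- 0L
  cap <- supine_sbp - dmin_sbp <= supine_dbp - dmax_dbp   # lowest sbp <= highest dbp
  if (any(cap)) {
    repairs <- repairs + sum(cap)
    dmin_sbp[cap] <- pmin(dmin_sbp[cap],
                          supine_sbp[cap] - (supine_dbp[cap] - dmax_dbp[cap]) - 5)
  }
  floor_bad <- supine_dbp - dmin_dbp <= 5                 # lowest dbp near zero
  if (any(floor_bad)) {
    repairs <- repairs + sum(floor_bad)
    dmin_dbp[floor_bad] <- supine_dbp[floor_bad] - 6
  }
  ceil_bad <- supine_sbp - dmax_sbp >= 295                # highest sbp near 300
  if (any(ceil_bad)) {
    repairs <- repairs + sum(ceil_bad)
    dmax_sbp[ceil_bad] <- supine_sbp[ceil_bad] - 294
  }
  dmax_sbp <- pmin(dmax_sbp, dmin_sbp)
  dmax_dbp <- pmin(dmax_dbp, dmin_dbp)

  burden <- params$theta_ac * hm_c + params$theta_bc * (dmin_sbp - params$b0_sbp) +
    params$beta_age_c * age_c + params$beta_dur_c * dur_c +
    stats::rnorm(n, 0, params$sigma_burden)
  burden_z <- as.numeric(scale(burden))

  cat <- instrument_catalogue()
  scores <- lapply(seq_len(nrow(cat)), function(i) {
    with(cat[i, ], {
      raw <- mean + sd * (loading_sign * params$lambda * burden_z +
                          sqrt(1 - params$lambda^2) * stats::rnorm(n))
      pmin(pmax(round(raw), min), max)
    })
  })
  names(scores) <- cat$name

  cohort <- data.frame(patient_id = id, age = age, sex = sex,
                       duration = duration, early_hm = early_hm,
                       delayed_hm = delayed_hm, latent_burden = burden,
                       stringsAsFactors = FALSE)
  cohort <- cbind(cohort, as.data.frame(scores))
  cohort$target_supine_sbp <- supine_sbp
  cohort$target_supine_dbp <- supine_dbp
  cohort$target_dmin_sbp <- dmin_sbp
  cohort$target_dmin_dbp <- dmin_dbp
  cohort$target_dmax_sbp <- dmax_sbp
  cohort$target_dmax_dbp <- dmax_dbp
  attr(cohort, "n_bp_repairs") <- repairs

  tilt <- construct_tilt_series(id, supine_sbp, supine_dbp,
                                dmin_sbp, dmin_dbp, dmax_sbp, dmax_dbp)
  list(cohort = cohort, tilt = tilt)
}
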