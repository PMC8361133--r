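# Cardiac MIBG scintigraphy metrics.  Uptake is measured in regions of
# interest drawn around the heart and the mediastinum at an early (30-min)
# and a delayed (2-h) time point; a delayed H/M ratio below the
# site-calibrated reference limit (1.78 here) marks cardiac sympathetic
# denervation.

#' Heart-to-mediastinum uptake ratio
#'
#' @param heart_uptake,mediastinum_uptake Positive tracer counts from the
#'   cardiac and mediastinal regions of interest; vectorized.
#' @return Dimensionless H/M ratio.
#' @export
#' @examples
#' hm_ratio(200, 100)
hm_ratio <- function(heart_uptake, mediastinum_uptake) {
  if (any(!is.finite(heart_uptake)) || any(!is.finite(mediastinum_uptake)) ||
      any(heart_uptake <= 0) || any(mediastinum_uptake <= 0)) {
    stop("heart and mediastinum uptakes must be positive", call. = FALSE)
  }
  heart_uptake / mediastinum_uptake
}

#' MIBG washout rate
#'
#' `100 * (early - delayed) / early`, in percent. Negative when delayed
#' uptake exceeds early uptake (typical of preserved sympathetic tone);
#' zero when the two ratios are equal.
#'
#' @param early_hm,delayed_hm Early and delayed H/M ratios; vectorized.
#' @return Washout rate in percent.
#' @export
#' @examples
#' washout_rate(2.0, 1.5)   # 25
#' washout_rate(1.96, 2.04) # negative: delayed exceeds early
washout_rate <- function(early_hm, delayed_hm) {
  if (any(!is.finite(early_hm)) || any(early_hm <= 0)) {
    stop("early H/M ratio must be positive", call. = FALSE)
  }
  100 * (early_hm - delayed_hm) / early_hm
}

#' Classify MIBG uptake as normal or abnormal
#'
#' A delayed H/M ratio strictly below `cutoff` is abnormal (cardiac
#' sympathetic denervation); a ratio at or above the cutoff is normal.
#'
#' @param delayed_hm Delayed H/M ratio; vectorized.
#' @param cutoff Lower reference limit for the delayed H/M ratio
#'   (site-calibrated; default 1.78).
#' @return Character vector, `"normal"` or `"abnormal"`.
#' @export
classify_mibg <- function(delayed_hm, cutoff = 1.78) {
  if (any(!is.finite(delayed_hm)) || any(delayed_hm <= 0)) {
    stop("delayed H/M ratio must be positive", call. = FALSE)
  }
  ifelse(delayed_hm < cutoff, "abnormal", "normal")
}

#' Add MIBG metrics to a cohort table
#'
#' Computes `early_hm`/`delayed_hm` from region-of-interest counts when the
#' ratio columns are absent (columns `heart_early`, `mediastinum_early`,
#' `heart_delayed`, `mediastinum_delayed`), then appends `washout_rate` and
#' `mibg_class`.
#'
#' @param cohort Data frame with H/M ratio columns or ROI count columns.
#' @param cutoff Delayed H/M cutoff passed to [classify_mibg()].
#' @return `cohort` with columns `early_hm`, `delayed_hm`, `washout_rate`
#'   and `mibg_class` added (existing ratio columns are kept as-is).
#' @export
mibg_metrics <- function(cohort, cutoff = 1.78) {
  have_ratio <- all(c("early_hm", "delayed_hm") %in% names(cohort))
  count_cols <- c("heart_early", "mediastinum_early",
                  "heart_delayed", "mediastinum_delayed")
  if (!have_ratio) {
    if (!all(count_cols %in% names(cohort))) {
      stop("cohort must supply early_hm/delayed_hm ratios or the ROI count ",
           "columns ", paste(count_cols, collapse = ", "), call. = FALSE)
    }
    cohort$early_hm <- hm_ratio(cohort$heart_early, cohort$mediastinum_early)
    cohort$delayed_hm <- hm_ratio(cohort$heart_delayed, cohort$mediastinum_delayed)
  }
  cohort$washout_rate <- washout_rate(cohort$early_hm, cohort$delayed_hm)
  cohort$mibg_class <- classify_mibg(cohort$delayed_hm, cutoff)
  cohort
}
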