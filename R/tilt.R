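# Head-up tilt-test protocol: BP every 5 min supine for 20 min, then at
# 0, 3, 5, 10, 15, 20 min after tilting to 60 degrees.  Supine averages use
# the 5-20 min measurements only; the OH pool is {3, 5} min tilted and the
# OHT pool is {3, 5, 10, 15, 20} min tilted (the tilted 0-min reading is
# never used).

SUPINE_REQUIRED <- c(5, 10, 15, 20)
POOL_MIN <- c(3, 5)
POOL_MAX <- c(3, 5, 10, 15, 20)

#' Average supine blood pressure
#'
#' Arithmetic mean of the supine systolic and diastolic pressures measured at
#' 5, 10, 15 and 20 minutes. A 0-minute supine reading, if present, is
#' excluded (the first measurement is taken before full rest is reached).
#'
#' @param time_min Numeric vector of supine measurement times in minutes.
#' @param sbp,dbp Systolic/diastolic pressures (mmHg) at those times.
#' @return Named numeric vector `c(sbp = , dbp = )` in mmHg.
#' @export
#' @examples
#' supine_average(c(0, 5, 10, 15, 20), c(130, 120, 122, 118, 120),
#'                c(80, 70, 72, 68, 70))
supine_average <- function(time_min, sbp, dbp) {
  missing_t <- setdiff(SUPINE_REQUIRED, time_min)
  if (length(missing_t) > 0L) {
    stop("missing required supine measurement at ",
         paste(missing_t, collapse = ", "), " min", call. = FALSE)
  }
  keep <- time_min %in% SUPINE_REQUIRED
  c(sbp = mean(sbp[keep]), dbp = mean(dbp[keep]))
}

#' Orthostatic blood-pressure drop (supine average minus tilted minimum)
#'
#' The lowest tilted SBP and DBP at 3 or 5 minutes are selected, each channel
#' independently, and subtracted from the supine averages. A positive delta is
#' a drop in standing BP; a negative delta is a rise.
#'
#' @param time_min,sbp,dbp Tilted-phase measurement times (min) and pressures
#'   (mmHg).
#' @param supine_avg Named vector from [supine_average()].
#' @return Named numeric vector `c(sbp = , dbp = )`: \eqn{\Delta}BPmin in mmHg.
#' @export
delta_min <- function(time_min, sbp, dbp, supine_avg) {
  keep <- time_min %in% POOL_MIN
  if (!any(keep)) {
    stop("no tilted measurement at 3 or 5 min; cannot evaluate orthostatic hypotension",
         call. = FALSE)
  }
  if (sum(keep) < length(POOL_MIN)) {
    warning("tilted 3/5-min pool incomplete; using ", sum(keep),
            " of 2 time points", call. = FALSE)
  }
  c(sbp = unname(supine_avg["sbp"]) - min(sbp[keep]),
    dbp = unname(supine_avg["dbp"]) - min(dbp[keep]))
}

#' Orthostatic blood-pressure rise (supine average minus tilted maximum)
#'
#' The highest tilted SBP and DBP among the 3, 5, 10, 15 and 20 minute
#' readings are selected per channel and subtracted from the supine averages.
#' By the sign convention a BP rise on standing gives a negative delta.
#'
#' @inheritParams delta_min
#' @return Named numeric vector `c(sbp = , dbp = )`: \eqn{\Delta}BPmax in mmHg.
#' @export
delta_max <- function(time_min, sbp, dbp, supine_avg) {
  keep <- time_min %in% POOL_MAX
  if (!any(keep)) {
    stop("no tilted measurement at 3-20 min; cannot evaluate orthostatic hypertension",
         call. = FALSE)
  }
  if (sum(keep) < length(POOL_MAX)) {
    warning("tilted 3-20-min pool incomplete; using ", sum(keep),
            " of 5 time points", call. = FALSE)
  }
  c(sbp = unname(supine_avg["sbp"]) - max(sbp[keep]),
    dbp = unname(supine_avg["dbp"]) - max(dbp[keep]))
}

#' Supine hypertension
#'
#' SH is an average supine BP of at least 140 mmHg systolic and/or 90 mmHg
#' diastolic.
#'
#' @param supine_avg_sbp,supine_avg_dbp Average supine pressures (mmHg);
#'   vectorized.
#' @param sbp_cut,dbp_cut Thresholds (mmHg), inclusive.
#' @return Logical vector.
#' @export
classify_sh <- function(supine_avg_sbp, supine_avg_dbp,
                        sbp_cut = 140, dbp_cut = 90) {
  supine_avg_sbp >= sbp_cut | supine_avg_dbp >= dbp_cut
}

#' Orthostatic hypotension
#'
#' OH is a drop of at least 20/10 mmHg (systolic/diastolic, and/or) within
#' 5 minutes of tilt; in patients with supine hypertension the stricter
#' 30/15 mmHg thresholds apply.
#'
#' @param delta_sbp_min,delta_dbp_min \eqn{\Delta}BPmin from [delta_min()]
#'   (mmHg, positive = drop); vectorized.
#' @param sh Logical: supine hypertension, from [classify_sh()].
#' @return Logical vector.
#' @export
classify_oh <- function(delta_sbp_min, delta_dbp_min, sh) {
  ifelse(sh,
         delta_sbp_min >= 30 | delta_dbp_min >= 15,
         delta_sbp_min >= 20 | delta_dbp_min >= 10)
}

#' Orthostatic hypertension
#'
#' In patients with supine hypertension, OHT requires a BP rise of at least
#' 20/10 mmHg (\eqn{\Delta}BPmax of \eqn{\le} \eqn{-}20 systolic and/or
#' \eqn{\le} \eqn{-}10 diastolic). Without supine hypertension, OHT is met
#' either by that rise or by a highest tilted BP of at least 140/90 mmHg.
#'
#' @param delta_sbp_max,delta_dbp_max \eqn{\Delta}BPmax from [delta_max()]
#'   (mmHg, negative = rise); vectorized.
#' @param highest_tilted_sbp,highest_tilted_dbp Maximum tilted pressures
#'   (mmHg) over the 3-20 min pool.
#' @param sh Logical: supine hypertension.
#' @return Logical vector.
#' @export
classify_oht <- function(delta_sbp_max, delta_dbp_max,
                         highest_tilted_sbp, highest_tilted_dbp, sh) {
  rise <- delta_sbp_max <= -20 | delta_dbp_max <= -10
  ifelse(sh, rise,
         rise | highest_tilted_sbp >= 140 | highest_tilted_dbp >= 90)
}

validate_tilt <- function(tilt) {
  req <- c("patient_id", "phase", "time_min", "sbp", "dbp")
  missing_c <- setdiff(req, names(tilt))
  if (length(missing_c) > 0L) {
    stop("tilt table is missing required column(s): ",
         paste(missing_c, collapse = ", "), call. = FALSE)
  }
  if (nrow(tilt) == 0L) stop("tilt table is empty", call. = FALSE)
  bad_phase <- !tilt$phase %in% c("supine", "tilt")
  if (any(bad_phase)) {
    stop("invalid phase value(s): ",
         paste(unique(tilt$phase[bad_phase]), collapse = ", "),
         " (expected 'supine' or 'tilt')", call. = FALSE)
  }
  for (col in c("time_min", "sbp", "dbp")) {
    if (!is.numeric(tilt[[col]])) {
      stop("column '", col, "' must be numeric", call. = FALSE)
    }
  }
  bad_bp <- which(!(tilt$dbp > 0 & tilt$dbp < tilt$sbp & tilt$sbp < 300))
  if (length(bad_bp) > 0L) {
    stop("implausible BP at row(s) ", paste(utils::head(bad_bp, 5L), collapse = ", "),
         ": require 0 < dbp < sbp < 300", call. = FALSE)
  }
  key <- paste(tilt$patient_id, tilt$phase, tilt$time_min, sep = "|")
  dup <- key[duplicated(key)]
  if (length(dup) > 0L) {
    stop("duplicate (patient, phase, time) measurement(s): ",
         paste(utils::head(unique(dup), 5L), collapse = "; "), call. = FALSE)
  }
  invisible(tilt)
}

profile_one <- function(time_min, sbp, dbp, phase, patient_id) {
  sup <- phase == "supine"
  res <- tryCatch({
    avg <- supine_average(time_min[sup], sbp[sup], dbp[sup])
    dmin <- delta_min(time_min[!sup], sbp[!sup], dbp[!sup], avg)
    dmax <- delta_max(time_min[!sup], sbp[!sup], dbp[!sup], avg)
    sh <- classify_sh(avg["sbp"], avg["dbp"])
    hi_sbp <- avg["sbp"] - dmax["sbp"]
    hi_dbp <- avg["dbp"] - dmax["dbp"]
    data.frame(
      patient_id = patient_id,
      supine_avg_sbp = unname(avg["sbp"]),
      supine_avg_dbp = unname(avg["dbp"]),
      delta_sbp_min = unname(dmin["sbp"]),
      delta_dbp_min = unname(dmin["dbp"]),
      delta_sbp_max = unname(dmax["sbp"]),
      delta_dbp_max = unname(dmax["dbp"]),
      sh = unname(sh),
      oh = unname(classify_oh(dmin["sbp"], dmin["dbp"], sh)),
      oht = unname(classify_oht(dmax["sbp"], dmax["dbp"], hi_sbp, hi_dbp, sh)),
      stringsAsFactors = FALSE
    )
  }, error = function(e) {
    stop("patient ", patient_id, ": ", conditionMessage(e), call. = FALSE)
  })
  res
}

#' Orthostatic profiles for a cohort of tilt-test series
#'
#' Computes, for every patient in a long-format tilt table, the average supine
#' BP, the four orthostatic delta quantities (\eqn{\Delta}SBPmin,
#' \eqn{\Delta}DBPmin, \eqn{\Delta}SBPmax, \eqn{\Delta}DBPmax) and the supine
#' hypertension (SH), orthostatic hypotension (OH) and orthostatic
#' hypertension (OHT) flags. OH and OHT are not mutually exclusive.
#'
#' @param tilt Data frame with columns `patient_id`, `phase`
#'   (`"supine"`/`"tilt"`), `time_min`, `sbp`, `dbp` — one row per
#'   measurement.
#' @return Data frame, one row per patient, with columns `patient_id`,
#'   `supine_avg_sbp`, `supine_avg_dbp`, `delta_sbp_min`, `delta_dbp_min`,
#'   `delta_sbp_max`, `delta_dbp_max`, `sh`, `oh`, `oht`.
#' @seealso [supine_average()], [delta_min()], [delta_max()],
#'   [classify_sh()], [classify_oh()], [classify_oht()]
#' @export
tilt_profiles <- function(tilt) {
  validate_tilt(tilt)
  idx <- split(seq_len(nrow(tilt)), tilt$patient_id)
  ids <- names(idx)
  time_min <- tilt$time_min; sbp <- tilt$sbp; dbp <- tilt$dbp
  phase <- tilt$phase
  out <- vector("list", length(idx))
  for (k in seq_along(idx)) {
    i <- idx[[k]]
    out[[k]] <- profile_one(time_min[i], sbp[i], dbp[i], phase[i], ids[k])
  }
  res <- do.call(rbind, out)
  # split() orders by factor level; restore first-appearance order
  first <- match(unique(as.character(tilt$patient_id)), res$patient_id)
  res <- res[first, , drop = FALSE]
  rownames(res) <- NULL
  res
}
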