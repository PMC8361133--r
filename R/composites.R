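# Composite severity scores.  Each rating-scale total is standardized to a
# cohort z-score (sample SD, n-1); domain composites average the component
# z-scores.  Higher z = worse severity throughout.

#' Cohort z-standardization of a score column
#'
#' Centers and scales to sample mean 0 and sample SD 1 (denominator n-1).
#' Missing values are ignored when estimating the mean and SD and propagate
#' to the output.
#'
#' @param values Numeric vector of scale totals.
#' @param name Instrument name used in error messages.
#' @return Numeric vector of z-scores.
#' @export
#' @examples
#' zscore_column(c(0, 10))
zscore_column <- function(values, name = deparse(substitute(values))) {
  ok <- !is.na(values)
  if (sum(ok) < 2L) {
    stop("cannot z-score '", name, "': fewer than 2 observed values",
         call. = FALSE)
  }
  s <- stats::sd(values[ok])
  if (!is.finite(s) || s == 0) {
    stop("cannot z-score '", name, "': zero variance", call. = FALSE)
  }
  (values - mean(values[ok])) / s
}

# Mean of available component z's per patient when at least half are
# observed, else NA.
composite_mean <- function(zmat) {
  n_obs <- rowSums(!is.na(zmat))
  out <- rowMeans(zmat, na.rm = TRUE)
  out[n_obs < ncol(zmat) / 2] <- NA_real_
  out[n_obs == 0L] <- NA_real_
  out
}

#' Default instrument set of the global composite score
#'
#' The ten motor and nonmotor assessment totals averaged (as cohort
#' z-scores) into the global burden composite: UPDRS parts II and III, NMSS,
#' MADRS, ESS, PDSS-2, RBDSQ, SCOPA-AUT (sexual subsection excluded from its
#' total), and OHQ parts I and II (summed separately).
#'
#' @return Character vector of column names.
#' @export
global_instruments <- function() {
  c("updrs_ii", "updrs_iii", "nmss", "madrs", "ess", "pdss2",
    "rbdsq", "scopa_aut", "ohq_i", "ohq_ii")
}

#' Motor, sleep, autonomic and global composite z-scores
#'
#' Standardizes each questionnaire total to a cohort z-score and appends four
#' composites: motor (mean z of UPDRS II and III), sleep (ESS, PDSS-2,
#' RBDSQ), autonomic (OHQ I, OHQ II, SCOPA-AUT) and global (mean z over
#' `global_set`). Higher z-scores indicate worse severity. A patient's
#' composite is the mean of the component z-scores observed for that patient
#' when at least half are present, else `NA`.
#'
#' @param cohort Data frame holding the questionnaire total columns.
#' @param global_set Instrument columns entering the global composite
#'   (default [global_instruments()]).
#' @param ohq_mode `"separate"` (default): OHQ parts I and II contribute one
#'   z-column each to the autonomic and global composites; `"combined"`: a
#'   single z of their sum is used instead.
#' @return `cohort` with columns `motor_z`, `sleep_z`, `autonomic_z`,
#'   `global_z` added.
#' @export
add_composites <- function(cohort, global_set = global_instruments(),
                           ohq_mode = c("separate", "combined")) {
  ohq_mode <- match.arg(ohq_mode)
  motor_set <- c("updrs_ii", "updrs_iii")
  sleep_set <- c("ess", "pdss2", "rbdsq")
  if (ohq_mode == "separate") {
    autonomic_set <- c("ohq_i", "ohq_ii", "scopa_aut")
  } else {
    if (all(c("ohq_i", "ohq_ii") %in% names(cohort)) &&
        !"ohq_total" %in% names(cohort)) {
      cohort$ohq_total <- cohort$ohq_i + cohort$ohq_ii
    }
    autonomic_set <- c("ohq_total", "scopa_aut")
    global_set <- unique(c(setdiff(global_set, c("ohq_i", "ohq_ii")),
                           "ohq_total"))
  }
  needed <- unique(c(motor_set, sleep_set, autonomic_set, global_set))
  missing_c <- setdiff(needed, names(cohort))
  if (length(missing_c) > 0L) {
    stop("cohort is missing instrument column(s): ",
         paste(missing_c, collapse = ", "), call. = FALSE)
  }
  z <- sapply(needed, function(v) zscore_column(cohort[[v]], v))
  z <- matrix(z, nrow = nrow(cohort), dimnames = list(NULL, needed))
  cohort$motor_z <- composite_mean(z[, motor_set, drop = FALSE])
  cohort$sleep_z <- composite_mean(z[, sleep_set, drop = FALSE])
  cohort$autonomic_z <- composite_mean(z[, autonomic_set, drop = FALSE])
  cohort$global_z <- composite_mean(z[, global_set, drop = FALSE])
  cohort
}
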