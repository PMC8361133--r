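# CSV input with validation, and the pipeline driver chaining
# classification -> MIBG metrics -> composites -> group comparisons ->
# mediation models.

read_validated_csv <- function(path, required, numeric_cols, what) {
  if (!file.exists(path)) stop(what, " file not found: ", path, call. = FALSE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  missing_c <- setdiff(required, names(tab))
  if (length(missing_c) > 0L) {
    stop(what, " file ", path, " is missing required column(s): ",
         paste(missing_c, collapse = ", "),
         " (expected at least: ", paste(required, collapse = ", "), ")",
         call. = FALSE)
  }
  for (col in intersect(numeric_cols, names(tab))) {
    v <- tab[[col]]
    if (!is.numeric(v)) {
      coerced <- suppressWarnings(as.numeric(v))
      bad <- which(is.na(coerced) & !is.na(v) & v != "")
      if (length(bad) > 0L) {
        stop(what, " file ", path, ": non-numeric '", col, "' at data row(s) ",
             paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
      }
      tab[[col]] <- coerced
    }
  }
  tab
}

#' Read a cohort table from CSV
#'
#' @param path CSV file with one row per patient; must contain `patient_id`
#'   and the columns in `required`.
#' @param required Additional required columns (default the MIBG ratio
#'   columns and the covariates used by the default mediation models).
#' @return Data frame.
#' @export
read_cohort <- function(path,
                        required = c("age", "duration",
                                     "early_hm", "delayed_hm")) {
  tab <- read_validated_csv(path, c("patient_id", required),
                            numeric_cols = setdiff(c(required,
                              global_instruments()), "patient_id"),
                            what = "cohort")
  if (anyDuplicated(tab$patient_id)) {
    stop("cohort file ", path, " has duplicated patient_id value(s): ",
         paste(utils::head(unique(tab$patient_id[duplicated(tab$patient_id)]), 5L),
               collapse = ", "), call. = FALSE)
  }
  tab
}

#' Read a long-format tilt-test table from CSV
#'
#' @param path CSV with columns `patient_id`, `phase` (`supine`/`tilt`),
#'   `time_min`, `sbp`, `dbp`, one row per measurement.
#' @return Validated data frame (see [tilt_profiles()] for the checks).
#' @export
read_tilt <- function(path) {
  tab <- read_validated_csv(path,
                            c("patient_id", "phase", "time_min", "sbp", "dbp"),
                            numeric_cols = c("time_min", "sbp", "dbp"),
                            what = "tilt")
  validate_tilt(tab)
}

#' Run the full analysis pipeline on a cohort
#'
#' Chains the analysis stages in protocol order: tilt-test classification
#' ([tilt_profiles()]), MIBG metrics ([mibg_metrics()]), composite scores
#' ([add_composites()]), the MIBG-group comparison table
#' ([compare_groups()]) and the mediation models ([mediate()]) — by default
#' every combination of outcome in `outcomes` and mediator in `mediators`
#' for each predictor in `predictors`, mirroring a primary analysis on the
#' global composite and subdomain analyses on the motor, sleep and autonomic
#' composites, with the early H/M ratio and washout rate available as
#' alternative exposure measures.
#'
#' @param cohort Cohort data frame (or path to a cohort CSV).
#' @param tilt Long-format tilt table (or path to a tilt CSV).
#' @param predictors,mediators,outcomes Character vectors defining the grid
#'   of mediation models.
#' @param covariates Covariates for every mediation model.
#' @param mibg_cutoff Delayed H/M cutoff for [classify_mibg()].
#' @param n_boot Bootstrap resamples per mediation model.
#' @param seed Top-level seed; model `k` of the grid uses `seed + k` so the
#'   whole bundle is reproducible.
#' @param compare_vars Variables for the group-comparison table (default: a
#'   compact set of severity and orthostatic measures present in the data).
#' @param out_dir Optional directory; when given, writes `profiles.csv`,
#'   `cohort_scored.csv`, `table1.csv`, `mediation.json` and `run_log.json`.
#' @return List of class `"orthomediate_pipeline"` with elements `cohort`
#'   (scored), `profiles`, `table1`, `mediation` (named list of
#'   [mediate()] fits), and `meta`.
#' @export
run_pipeline <- function(cohort, tilt,
                         predictors = "delayed_hm",
                         mediators = c("delta_sbp_min", "delta_dbp_min"),
                         outcomes = c("global_z", "motor_z",
                                      "sleep_z", "autonomic_z"),
                         covariates = c("age", "duration"),
                         mibg_cutoff = 1.78,
                         n_boot = 1000,
                         seed = 1,
                         compare_vars = NULL,
                         out_dir = NULL) {
  if (is.character(cohort)) cohort <- read_cohort(cohort)
  if (is.character(tilt)) tilt <- read_tilt(tilt)
  if (nrow(cohort) == 0L) stop("cohort is empty", call. = FALSE)

  profiles <- tilt_profiles(tilt)
  scored <- merge(cohort, profiles, by = "patient_id", sort = FALSE)
  if (nrow(scored) < nrow(cohort)) {
    warning(nrow(cohort) - nrow(scored),
            " patient(s) dropped: no tilt series found", call. = FALSE)
  }
  scored <- mibg_metrics(scored, cutoff = mibg_cutoff)
  scored <- add_composites(scored)

  if (is.null(compare_vars)) {
    candidates <- c("age", "duration", "updrs_ii", "updrs_iii",
                    "delta_sbp_min", "delta_dbp_min", "delta_sbp_max",
                    "delta_dbp_max", "washout_rate", "global_z", "motor_z",
                    "sleep_z", "autonomic_z", "sh", "oh", "oht")
    compare_vars <- intersect(candidates, names(scored))
  }
  table1 <- compare_groups(scored, "mibg_class", compare_vars)

  grid <- expand.grid(predictor = predictors, mediator = mediators,
                      outcome = outcomes, stringsAsFactors = FALSE)
  fits <- vector("list", nrow(grid))
  for (k in seq_len(nrow(grid))) {
    fits[[k]] <- mediate(scored,
                         outcome = grid$outcome[k],
                         predictor = grid$predictor[k],
                         mediator = grid$mediator[k],
                         covariates = covariates,
                         n_boot = n_boot,
                         seed = if (is.null(seed)) NULL else seed + k)
  }
  names(fits) <- paste(grid$outcome, grid$predictor, grid$mediator, sep = "~")

  meta <- list(n_patients = nrow(scored), mibg_cutoff = mibg_cutoff,
               n_boot = n_boot, seed = seed,
               package_version = as.character(utils::packageVersion("orthomediate")),
               grid = grid)
  bundle <- structure(list(cohort = scored, profiles = profiles,
                           table1 = table1, mediation = fits, meta = meta),
                      class = "orthomediate_pipeline")
  if (!is.null(out_dir)) write_pipeline(bundle, out_dir)
  bundle
}

mediation_report <- function(fit) {
  eff <- fit$effects
  list(effects = cbind(effect = rownames(eff),
                       as.data.frame(round(eff, 3))),
       n_used = fit$n_used, n_boot = fit$n_boot,
       ci_level = fit$ci_level, seed = fit$boot_seed,
       variables = fit$variables)
}

write_pipeline <- function(bundle, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(bundle$profiles, file.path(out_dir, "profiles.csv"),
                   row.names = FALSE)
  utils::write.csv(bundle$cohort, file.path(out_dir, "cohort_scored.csv"),
                   row.names = FALSE)
  utils::write.csv(bundle$table1, file.path(out_dir, "table1.csv"),
                   row.names = FALSE)
  jsonlite::write_json(lapply(bundle$mediation, mediation_report),
                       file.path(out_dir, "mediation.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  jsonlite::write_json(bundle$meta, file.path(out_dir, "run_log.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(out_dir)
}

#' @export
print.orthomediate_pipeline <- function(x, ...) {
  cat("orthomediate pipeline bundle\n")
  cat("  patients: ", x$meta$n_patients, "\n", sep = "")
  cat("  comparison table: ", nrow(x$table1), " variables by mibg_class\n",
      sep = "")
  cat("  mediation models (", x$meta$n_boot, " bootstrap resamples each):\n",
      sep = "")
  for (nm in names(x$mediation)) {
    ind <- x$mediation[[nm]]$effects["indirect", ]
    tot <- x$mediation[[nm]]$effects["total", ]
    cat(sprintf("    %-38s total %7.3f [%.3f, %.3f]  indirect %7.3f [%.3f, %.3f]\n",
                nm, tot$estimate, tot$ci_low, tot$ci_high,
                ind$estimate, ind$ci_low, ind$ci_high))
  }
  invisible(x)
}
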