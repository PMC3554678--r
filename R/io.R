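TRIAL_COLUMNS <- c("subject_id", "trial_index", "condition",
                   "manipulation_deg", "preceding_manipulation_deg",
                   "instructed_amplitude_deg", "epd_deg", "mpd_deg",
                   "ppd_deg", "amplitude_deg", "max_dev_deg",
                   "peak_speed_deg_s", "status")

SAMPLE_COLUMNS <- c("subject_id", "trial_index", "t_s", "x_deg", "y_deg")

STATUS_LEVELS <- c("valid", "invalid_amplitude", "invalid_no_estimate",
                   "excluded_curvature", "excluded_velocity",
                   "discarded_follow")

ALLOWED_AMOUNTS <- c(0, 5, 10, 20, 40)

#' Read or write a trial table
#'
#' The trial CSV schema has one row per trial: `subject_id`, `trial_index`,
#' `condition` (`feedback`/`probe`), `manipulation_deg` (blank for probe
#' trials), `preceding_manipulation_deg` (blank for feedback trials),
#' `instructed_amplitude_deg`, `epd_deg`, `mpd_deg`, `ppd_deg`,
#' `amplitude_deg`, `max_dev_deg`, `peak_speed_deg_s`, `status`. Angles are
#' degrees, counterclockwise positive, 0 = rightward. Reading validates the
#' schema and reports offending row numbers; writing then reading a table is
#' lossless.
#'
#' @param path CSV file path.
#' @return `read_trials()` returns the validated trial table.
#' @export
read_trials <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(setdiff(TRIAL_COLUMNS, "ppd_deg"), names(d))
  if (length(missing_cols))
    stop("trials file missing columns: ", paste(missing_cols, collapse = ", "))
  if (nrow(d) == 0L) {
    d[TRIAL_COLUMNS[!TRIAL_COLUMNS %in% names(d)]] <- numeric(0)
    return(d[TRIAL_COLUMNS])
  }
  bad <- function(cond, what) {
    rows <- which(cond)
    if (length(rows))
      stop(sprintf("%s (rows %s)", what,
                   paste(utils::head(rows, 10L), collapse = ", ")))
  }
  bad(!d$condition %in% c("feedback", "probe"), "unknown condition value")
  bad(!d$status %in% STATUS_LEVELS, "unknown status value")
  num_cols <- c("manipulation_deg", "preceding_manipulation_deg",
                "instructed_amplitude_deg", "epd_deg", "mpd_deg",
                "amplitude_deg", "max_dev_deg", "peak_speed_deg_s")
  for (cl in num_cols)
    bad(!is.na(d[[cl]]) & !is.finite(suppressWarnings(as.numeric(d[[cl]]))),
        paste("non-numeric value in", cl))
  bad(d$condition == "feedback" & is.na(d$manipulation_deg),
      "feedback trial without manipulation")
  bad(d$condition == "probe" & is.na(d$preceding_manipulation_deg),
      "probe trial without preceding manipulation")
  bad(!is.na(d$manipulation_deg) &
        !abs(d$manipulation_deg) %in% ALLOWED_AMOUNTS,
      "manipulation outside the allowed set {0, +-5, +-10, +-20, +-40}")
  bad(!is.na(d$preceding_manipulation_deg) &
        !abs(d$preceding_manipulation_deg) %in% ALLOWED_AMOUNTS,
      "preceding manipulation outside the allowed set")
  for (cl in num_cols)
    d[[cl]] <- suppressWarnings(as.numeric(d[[cl]]))
  d$trial_index <- as.integer(d$trial_index)
  if (!"ppd_deg" %in% names(d))
    d$ppd_deg <- d$epd_deg - d$mpd_deg
  d$ppd_deg <- suppressWarnings(as.numeric(d$ppd_deg))
  d[TRIAL_COLUMNS]
}

#' @rdname read_trials
#' @param trials Trial table.
#' @export
write_trials <- function(trials, path) {
  utils::write.csv(trials[TRIAL_COLUMNS], path, row.names = FALSE,
                   na = "")
  invisible(path)
}

#' Read or write long-format trajectory samples
#'
#' One row per position sample: `subject_id`, `trial_index`, `t_s`, `x_deg`,
#' `y_deg`.
#'
#' @param path CSV file path.
#' @return `read_samples()` returns the samples table.
#' @export
read_samples <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(SAMPLE_COLUMNS, names(d))
  if (length(missing_cols))
    stop("samples file missing columns: ",
         paste(missing_cols, collapse = ", "))
  d[SAMPLE_COLUMNS]
}

#' @rdname read_samples
#' @param samples Samples table.
#' @export
write_samples <- function(samples, path) {
  utils::write.csv(samples[SAMPLE_COLUMNS], path, row.names = FALSE, na = "")
  invisible(path)
}

#' Write the generator-parameter sidecar
#'
#' Records the exact generator configuration (including the seed) next to a
#' simulated data set, as JSON.
#'
#' @param params A [generator_params()] object.
#' @param path Output JSON path.
#' @export
write_params <- function(params, path) {
  jsonlite::write_json(unclass(params), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a pipeline configuration file (YAML or JSON)
#'
#' The file may contain a `generator` section (passed to
#' [generator_params()]), an `analysis` section (thresholds, Bayes-factor
#' prior SD, alpha) and a top-level `seed` overriding the generator seed.
#'
#' @param path Configuration file (`.yaml`/`.yml` or `.json`).
#' @return A [pipeline_config()] object.
#' @export
read_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  gen <- raw$generator %||% list()
  if (!is.null(gen$attribution_weight_by_amount))
    gen$attribution_weight_by_amount <-
      unlist(gen$attribution_weight_by_amount)
  if (!is.null(gen$recal_gain_by_amount))
    gen$recal_gain_by_amount <- unlist(gen$recal_gain_by_amount)
  if (!is.null(raw$seed)) gen$seed <- raw$seed
  pipeline_config(generator = do.call(generator_params, gen),
                  analysis = do.call(analysis_settings,
                                     raw$analysis %||% list()))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
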