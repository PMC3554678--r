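#' Analysis settings
#'
#' Thresholds and inferential constants of the analysis stage. The defaults
#' are the standard constants of the paradigm: curvature exclusion above
#' 2.25 degrees, velocity exclusion above 120 degrees/s, amplitude validity
#' at half the instructed amplitude, feedback visible above 4.5 degrees,
#' half-normal Bayes-factor prior SD 0.5, alpha 0.05.
#'
#' @param curvature_threshold_deg,speed_threshold_deg_s,amplitude_validity_fraction,feedback_visibility_amplitude_deg
#'   See [analysis_thresholds()].
#' @param bf_prior_sd Half-normal prior SD for Bayes factors.
#' @param alpha Significance level (Mauchly trigger, per-subject regression
#'   significance).
#' @param include_veridical_in_overall_regression Whether probe trials
#'   following veridical feedback enter the all-manipulations trial-by-trial
#'   regression.
#' @return A list of settings.
#' @export
analysis_settings <- function(curvature_threshold_deg = 2.25,
                              speed_threshold_deg_s = 120,
                              amplitude_validity_fraction = 0.5,
                              feedback_visibility_amplitude_deg = 4.5,
                              bf_prior_sd = 0.5,
                              alpha = 0.05,
                              include_veridical_in_overall_regression = TRUE) {
  stopifnot(bf_prior_sd > 0, alpha > 0, alpha < 1)
  c(analysis_thresholds(curvature_threshold_deg, speed_threshold_deg_s,
                        amplitude_validity_fraction,
                        feedback_visibility_amplitude_deg),
    list(bf_prior_sd = bf_prior_sd, alpha = alpha,
         include_veridical_in_overall_regression =
           include_veridical_in_overall_regression))
}

#' Pipeline configuration
#'
#' @param generator A [generator_params()] object (used when no trial table
#'   is supplied to [run_pipeline()]).
#' @param analysis An [analysis_settings()] list.
#' @return An object of class `recalib_config`.
#' @export
pipeline_config <- function(generator = generator_params(),
                            analysis = analysis_settings()) {
  structure(list(generator = generator, analysis = analysis),
            class = "recalib_config")
}

#' Run the full analysis pipeline
#'
#' Executes simulate (optional) -> kinematic filtering -> offset correction
#' -> per-trial measures -> orientation pooling -> inference, and returns a
#' structured report. Inputs are either a synthetic cohort generated from
#' `config$generator` (default) or a user-supplied trial table (with
#' optional raw trajectory samples, from which kinematics are then
#' recomputed). The run is fully deterministic given the configuration.
#'
#' @param config A [pipeline_config()] object.
#' @param trials Optional trial table (see [read_trials()]).
#' @param samples Optional long-format trajectory samples paired with
#'   `trials`.
#' @param out_dir Optional directory; when given, the trial table, the
#'   summary tables (CSV) and a JSON summary plus the generator sidecar are
#'   written there.
#' @param verbose If `TRUE`, every exclusion decision is logged with the
#'   violated threshold and the measured value.
#' @return An object of class `recalib_report`; see Details.
#'
#' @details The report contains: `weights` / `recalibration` (per-amount
#' pooled across-subject mean, raw SE and within-subject SE),
#' `weight_cells` / `recal_cells` (pooled subject x amount means),
#' `anova_weight` / `anova_recal` (2 x 4 repeated-measures ANOVAs on the
#' unpooled cells), `contrasts_weight` / `contrasts_recal` (planned
#' one-tailed contrasts and one-sample tests), `regression` (per-subject
#' all-manipulation trial-by-trial regressions plus their aggregate),
#' `regression_by_amount` (per-amount aggregated within-subject r and
#' half-normal Bayes factors), `unimodality` (Shapiro-Wilk screen),
#' `motor_adaptation` (probe-trial motor condition means, their one-way
#' repeated-measures ANOVA and the condition-level motor/percept
#' correlation) and `trial_accounting`.
#' @export
run_pipeline <- function(config = pipeline_config(), trials = NULL,
                         samples = NULL, out_dir = NULL, verbose = FALSE) {
  cohort_params <- NULL
  if (is.null(trials)) {
    cohort <- generate_cohort(config$generator)
    trials <- cohort$trials
    samples <- cohort$samples
    cohort_params <- cohort$params
    trials <- classify_and_filter(trials, thresholds = config$analysis)
  } else {
    trials <- classify_and_filter(trials, samples = samples,
                                  thresholds = config$analysis)
  }
  if (verbose) log_exclusions(trials, config$analysis)
  trials <- offset_correct(trials)

  # per-trial quotients, pooled over orientation
  w_trials <- trial_measures(trials, "weight")
  r_trials <- trial_measures(trials, "recalibration")
  w_pooled <- pool_orientations(w_trials, "quotient")
  r_pooled <- pool_orientations(r_trials, "quotient")
  w_cells <- cell_means(w_pooled)
  r_cells <- cell_means(r_pooled)

  report <- list(
    weights = amount_summary(w_cells),
    recalibration = amount_summary(r_cells),
    weight_cells = w_cells,
    recal_cells = r_cells,
    anova_weight = rm_anova_2x4(cell_means(w_trials),
                                alpha = config$analysis$alpha),
    anova_recal = rm_anova_2x4(cell_means(r_trials),
                               alpha = config$analysis$alpha),
    contrasts_weight = planned_contrasts(w_cells),
    contrasts_recal = planned_contrasts(r_cells),
    regression = overall_regressions(trials, config$analysis),
    regression_by_amount = amount_regressions(trials, config$analysis),
    unimodality = unimodality_screen(w_pooled, config$analysis$alpha),
    motor_adaptation = motor_report(trials, config$analysis),
    trial_accounting = trial_accounting(trials)
  )
  class(report) <- "recalib_report"

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_trials(trials, file.path(out_dir, "trials.csv"))
    if (!is.null(samples))
      write_samples(samples, file.path(out_dir, "samples.csv"))
    if (!is.null(cohort_params))
      write_params(cohort_params, file.path(out_dir, "params.json"))
    utils::write.csv(report$weights,
                     file.path(out_dir, "relative_weights.csv"),
                     row.names = FALSE)
    utils::write.csv(report$recalibration,
                     file.path(out_dir, "relative_recalibration.csv"),
                     row.names = FALSE)
    utils::write.csv(report$regression$per_subject,
                     file.path(out_dir, "trial_regressions.csv"),
                     row.names = FALSE)
    jsonlite::write_json(report_summary(report),
                         file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  report
}

# matched (feedback, following probe) percept pairs among evaluable trials
percept_pairs <- function(trials) {
  ord <- order(trials$subject_id, trials$trial_index)
  tr <- trials[ord, ]
  n <- nrow(tr)
  prev <- c(NA, seq_len(n - 1L))
  is_pair <- tr$condition == "probe" & tr$status == "valid" &
    c(FALSE, tr$subject_id[-n] == tr$subject_id[-1]) &
    c(FALSE, tr$condition[-n] == "feedback") &
    c(FALSE, tr$status[-n] == "valid")
  i <- which(is_pair)
  data.frame(subject_id = tr$subject_id[i],
             m_prev = tr$preceding_manipulation_deg[i],
             fb_ppd = tr$ppd_corr_deg[i - 1L],
             probe_ppd = tr$ppd_corr_deg[i])
}

overall_regressions <- function(trials, analysis) {
  pairs <- percept_pairs(trials)
  if (!analysis$include_veridical_in_overall_regression)
    pairs <- pairs[pairs$m_prev != 0, ]
  per_subject <- do.call(rbind, lapply(split(pairs, pairs$subject_id),
    function(d) {
      fit <- trial_regression(d$fb_ppd, d$probe_ppd)
      data.frame(subject_id = d$subject_id[1L], r = fit$r,
                 slope = fit$slope, intercept = fit$intercept,
                 df = fit$df, p = fit$p,
                 significant = fit$p < analysis$alpha)
    }))
  rownames(per_subject) <- NULL
  agg <- aggregate_within_subject_r(per_subject$r)
  list(per_subject = per_subject,
       mean_r = agg$mean, se_r = agg$se,
       mean_slope = mean(per_subject$slope),
       se_slope = stats::sd(per_subject$slope) /
         sqrt(nrow(per_subject)),
       t = agg$t, df = agg$df, p = agg$p_raw,
       n_significant = sum(per_subject$significant))
}

# per-amount within-subject correlations: regressions are run per signed
# manipulation and the coefficients pooled across orientations (averaged
# within subject), then aggregated across subjects with one-tailed tests
# (Bonferroni over the amount family) and half-normal Bayes factors
amount_regressions <- function(trials, analysis) {
  pairs <- percept_pairs(trials)
  amounts <- sort(unique(abs(pairs$m_prev)))
  rows <- lapply(amounts, function(a) {
    sub <- pairs[abs(pairs$m_prev) == a, ]
    r_subj <- sapply(split(sub, sub$subject_id), function(d) {
      rs <- sapply(split(d, d$m_prev), function(dd) {
        if (nrow(dd) < 3L || stats::var(dd$fb_ppd) == 0 ||
            stats::var(dd$probe_ppd) == 0) return(NA_real_)
        trial_regression(dd$fb_ppd, dd$probe_ppd)$r
      })
      mean(rs, na.rm = TRUE)
    })
    if (sum(is.finite(r_subj)) < 3L)
      return(data.frame(amount = a, mean_r = NA_real_, se_r = NA_real_,
                        n_subjects = sum(is.finite(r_subj)), t = NA_real_,
                        df = NA_real_, p_raw = NA_real_,
                        p_bonferroni = NA_real_, bayes_factor = NA_real_))
    agg <- aggregate_within_subject_r(r_subj, family = length(amounts))
    bf <- if (is.finite(agg$se) && agg$se > 0)
      dienes_bayes_factor(agg$mean, agg$se, analysis$bf_prior_sd)$B
    else NA_real_
    data.frame(amount = a, mean_r = agg$mean, se_r = agg$se,
               n_subjects = agg$n, t = agg$t, df = agg$df,
               p_raw = agg$p_raw, p_bonferroni = agg$p_bonferroni,
               bayes_factor = bf)
  })
  do.call(rbind, rows)
}

motor_report <- function(trials, analysis) {
  motor <- motor_adaptation_summary(trials)
  sel <- trials$condition == "probe" & trials$status == "valid" &
    !is.na(trials$preceding_manipulation_deg)
  d <- trials[sel, ]
  per_subj <- stats::aggregate(
    d$mpd_deg,
    by = list(subject_id = d$subject_id,
              cond = d$preceding_manipulation_deg),
    FUN = mean)
  mat <- try(cells_to_matrix(
    data.frame(subject_id = per_subj$subject_id, amount = per_subj$cond,
               value = per_subj$x), "amount"), silent = TRUE)
  motor$anova <- if (inherits(mat, "try-error")) NULL
                 else rm_anova_oneway(mat, alpha = analysis$alpha)
  motor
}

log_exclusions <- function(trials, analysis) {
  bad <- trials[trials$status != "valid", ]
  if (nrow(bad) == 0L) return(invisible())
  for (i in seq_len(nrow(bad))) {
    detail <- switch(bad$status[i],
      invalid_amplitude = sprintf("amplitude %.2f < %.2f deg",
        bad$amplitude_deg[i],
        analysis$amplitude_validity_fraction *
          bad$instructed_amplitude_deg[i]),
      invalid_no_estimate = "no perceptual estimate",
      excluded_curvature = sprintf("chord deviation %.2f > %.2f deg",
        bad$max_dev_deg[i], analysis$curvature_threshold_deg),
      excluded_velocity = sprintf("peak speed %.1f > %.1f deg/s",
        bad$peak_speed_deg_s[i], analysis$speed_threshold_deg_s),
      discarded_follow = "preceding feedback trial not valid",
      "")
    message(sprintf("[filter] %s trial %d (%s): %s -- %s",
                    bad$subject_id[i], bad$trial_index[i], bad$condition[i],
                    bad$status[i], detail))
  }
  invisible()
}

trial_accounting <- function(trials) {
  acct <- as.data.frame(table(condition = trials$condition,
                              status = trials$status))
  names(acct)[3L] <- "n"
  acct$n <- as.integer(acct$n)
  acct <- acct[acct$n > 0 | acct$status == "valid", ]
  rownames(acct) <- NULL
  stopifnot(sum(acct$n) == nrow(trials))
  acct
}

report_summary <- function(report) {
  list(
    relative_weight = stats::setNames(as.list(report$weights$mean),
                                      report$weights$amount),
    relative_recalibration =
      stats::setNames(as.list(report$recalibration$mean),
                      report$recalibration$amount),
    mean_within_subject_r = report$regression$mean_r,
    mean_regression_slope = report$regression$mean_slope,
    n_subjects_significant_regression = report$regression$n_significant,
    bayes_factors_by_amount =
      stats::setNames(as.list(report$regression_by_amount$bayes_factor),
                      report$regression_by_amount$amount),
    motor_percept_correlation = report$motor_adaptation$r,
    unimodality_tenable = report$unimodality$n_tenable,
    unimodality_tested = report$unimodality$n_tested,
    trials_total = sum(report$trial_accounting$n),
    trials_valid = sum(report$trial_accounting$n[
      report$trial_accounting$status == "valid"])
  )
}

#' @export
print.recalib_report <- function(x, ...) {
  cat("<recalib_report>\n\nRelative weight of visual information ",
      "(pooled, mean +- SE across subjects):\n", sep = "")
  w <- x$weights
  for (i in seq_len(nrow(w)))
    cat(sprintf("  %3g deg: %5.3f +- %.3f\n", w$amount[i], w$mean[i], w$se[i]))
  cat("\nRelative recalibration (pooled):\n")
  r <- x$recalibration
  for (i in seq_len(nrow(r)))
    cat(sprintf("  %3g deg: %5.3f +- %.3f\n", r$amount[i], r$mean[i], r$se[i]))
  cat(sprintf("\nTrial-by-trial regression (probe ~ preceding feedback):\n"))
  cat(sprintf("  mean r = %.3f +- %.3f; mean slope = %.3f +- %.3f; %d/%d subjects significant\n",
              x$regression$mean_r, x$regression$se_r,
              x$regression$mean_slope, x$regression$se_slope,
              x$regression$n_significant, nrow(x$regression$per_subject)))
  cat("  Bayes factors by amount:",
      paste(sprintf("B(%g)=%.2f", x$regression_by_amount$amount,
                    x$regression_by_amount$bayes_factor), collapse = ", "),
      "\n")
  cat(sprintf("\nMotor/percept condition-level correlation: r(%d) = %.2f, p = %.3g\n",
              x$motor_adaptation$df, x$motor_adaptation$r,
              x$motor_adaptation$p))
  cat(sprintf("Unimodality screen: %d of %d cells tenable\n",
              x$unimodality$n_tenable, x$unimodality$n_tested))
  invisible(x)
}
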