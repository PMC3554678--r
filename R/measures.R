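#' Perceived pointing direction
#'
#' The perceived pointing direction is the difference between the estimated
#' and the motor pointing direction, PPD = EPD - MPD, in degrees,
#' counterclockwise positive. It is the relative perceptual bias of one
#' trial and carries the internally attributed component of the visual
#' prediction error.
#'
#' @param epd,mpd Estimated and motor pointing directions (degrees);
#'   vectorised.
#' @return PPD in degrees.
#' @export
perceived_pointing_direction <- function(epd, mpd) {
  epd - mpd
}

#' Offset-correct perceived pointing directions within subject
#'
#' Subtracts, per subject and condition, the mean PPD of the reference
#' trials: for feedback trials, valid trials with veridical feedback
#' (manipulation 0); for probe trials, valid trials preceded by veridical
#' feedback. This removes the systematic constant shift between estimated
#' and motor pointing direction. References are computed on valid trials
#' only; only valid trials receive corrected values (others get `NA`).
#'
#' @param trials Trial table with `ppd_deg` and `status` columns.
#' @return The table with a `ppd_corr_deg` column added.
#' @export
offset_correct <- function(trials) {
  trials$ppd_corr_deg <- NA_real_
  for (sid in unique(trials$subject_id)) {
    for (cond in c("feedback", "probe")) {
      sel <- trials$subject_id == sid & trials$condition == cond &
        trials$status == "valid"
      if (!any(sel)) next
      ref <- if (cond == "feedback") {
        sel & trials$manipulation_deg == 0
      } else {
        sel & trials$preceding_manipulation_deg == 0
      }
      if (!any(ref, na.rm = TRUE))
        stop(sprintf(
          "subject %s has no valid veridical reference trials for %s trials",
          sid, cond))
      trials$ppd_corr_deg[sel] <-
        trials$ppd_deg[sel] - mean(trials$ppd_deg[ref], na.rm = TRUE)
    }
  }
  trials
}

#' Relative weight of visual information
#'
#' The internally attributed share of the visual prediction error in a
#' feedback trial: the offset-corrected perceived pointing direction divided
#' by the feedback manipulation of the same trial. Equals 1 iff the percept
#' matches the rotation (entirely internal attribution) and 0 iff the
#' estimated and motor directions coincide (entirely external attribution).
#' Undefined for veridical feedback.
#'
#' @param ppd_corrected Offset-corrected PPD (degrees); vectorised.
#' @param manipulation Feedback rotation of the same trial (degrees, non-zero).
#' @return Dimensionless quotient.
#' @export
relative_visual_weight <- function(ppd_corrected, manipulation) {
  if (any(manipulation == 0, na.rm = TRUE))
    stop("relative visual weight is undefined for veridical feedback (m = 0)")
  ppd_corrected / manipulation
}

#' Relative recalibration of the internal sensory prediction
#'
#' The offset-corrected perceived pointing direction of a probe trial
#' divided by the manipulation applied in the immediately preceding feedback
#' trial: the single-trial perceptual aftereffect, with the same 1/0
#' boundary semantics as the relative visual weight.
#'
#' @param ppd_corrected_probe Offset-corrected probe-trial PPD (degrees).
#' @param preceding_manipulation Rotation of the preceding feedback trial
#'   (degrees, non-zero).
#' @return Dimensionless quotient.
#' @export
relative_recalibration <- function(ppd_corrected_probe,
                                   preceding_manipulation) {
  if (any(preceding_manipulation == 0, na.rm = TRUE))
    stop("relative recalibration is undefined after veridical feedback (m = 0)")
  ppd_corrected_probe / preceding_manipulation
}

#' Per-trial measure table for a filtered, offset-corrected cohort
#'
#' Builds the per-trial quotient table that downstream cell means, ANOVAs
#' and the unimodality screen operate on: one row per evaluable trial with
#' subject, orientation (counterclockwise for positive rotations, clockwise
#' for negative), absolute amount of manipulation, and the measure value
#' (relative visual weight for feedback trials, relative recalibration for
#' probe trials). Veridical trials carry no quotient and are omitted.
#'
#' @param trials Offset-corrected trial table (see [offset_correct()]).
#' @param measure `"weight"` (valid feedback trials) or `"recalibration"`
#'   (valid probe trials).
#' @return Data frame with columns `subject_id`, `orientation`, `amount`,
#'   `value`.
#' @export
trial_measures <- function(trials, measure = c("weight", "recalibration")) {
  measure <- match.arg(measure)
  if (measure == "weight") {
    sel <- trials$condition == "feedback" & trials$status == "valid" &
      !is.na(trials$manipulation_deg) & trials$manipulation_deg != 0
    m <- trials$manipulation_deg[sel]
    value <- relative_visual_weight(trials$ppd_corr_deg[sel], m)
  } else {
    sel <- trials$condition == "probe" & trials$status == "valid" &
      !is.na(trials$preceding_manipulation_deg) &
      trials$preceding_manipulation_deg != 0
    m <- trials$preceding_manipulation_deg[sel]
    value <- relative_recalibration(trials$ppd_corr_deg[sel], m)
  }
  data.frame(subject_id = trials$subject_id[sel],
             orientation = ifelse(m > 0, "ccw", "cw"),
             amount = abs(m),
             value = value)
}

#' Pool measure values across manipulation orientations
#'
#' Combines counterclockwise and clockwise cells of the same absolute amount
#' of manipulation. Raw PPD values are sign-flipped in the clockwise cells
#' before concatenation (`type = "ppd"`); quotient measures (weight,
#' recalibration) are already sign-normalised by their definition and are
#' concatenated unchanged (`type = "quotient"`).
#'
#' @param measures Data frame with columns `subject_id`, `orientation`
#'   (`"ccw"`/`"cw"`), `amount`, `value`.
#' @param type `"quotient"` or `"ppd"`.
#' @return The same data frame with orientation dropped.
#' @export
pool_orientations <- function(measures, type = c("quotient", "ppd")) {
  type <- match.arg(type)
  value <- measures$value
  if (type == "ppd")
    value <- ifelse(measures$orientation == "cw", -value, value)
  data.frame(subject_id = measures$subject_id,
             amount = measures$amount,
             value = value)
}

#' Subject-level cell means
#'
#' Averages per-trial measure values within subject and cell. Cells are
#' `orientation x amount` for the unpooled table and `amount` for the pooled
#' one; these subject-level means are the ANOVA/contrast units.
#'
#' @param measures Per-trial table from [trial_measures()] or
#'   [pool_orientations()].
#' @return Data frame of subject-level means with an `n_trials` column.
#' @export
cell_means <- function(measures) {
  cols <- intersect(c("subject_id", "orientation", "amount"), names(measures))
  agg <- stats::aggregate(measures$value, by = measures[cols],
                          FUN = mean)
  names(agg)[ncol(agg)] <- "value"
  n <- stats::aggregate(measures$value, by = measures[cols],
                        FUN = length)
  agg$n_trials <- n$x
  agg[do.call(order, agg[cols]), , drop = FALSE]
}

#' Across-subject summary of pooled cell means
#'
#' @param cells Pooled subject-level means (columns `subject_id`, `amount`,
#'   `value`).
#' @return Data frame with per-amount mean, raw standard error, and
#'   within-subject (Masson-Loftus normalised) standard error across
#'   subjects.
#' @export
amount_summary <- function(cells) {
  wide <- cells_to_matrix(cells, "amount")
  norm <- masson_loftus_normalize(wide)
  data.frame(
    amount = as.numeric(colnames(wide)),
    mean = colMeans(wide),
    se = apply(wide, 2, stats::sd) / sqrt(nrow(wide)),
    se_within = apply(norm, 2, stats::sd) / sqrt(nrow(norm)),
    n_subjects = nrow(wide),
    row.names = NULL
  )
}

#' Motor adaptation summary over probe trials
#'
#' Per preceding-manipulation condition (all nine signed rotations), the
#' across-subject mean motor pointing direction and mean offset-corrected
#' perceived pointing direction in valid probe trials, and the Pearson
#' correlation between the two sets of condition means at the population
#' level (means are first taken within subject, then across subjects;
#' df = number of conditions - 2). Motor adaptation that compensates the
#' recalibrated visual consequence shows up as a negative correlation.
#'
#' @param trials Offset-corrected trial table.
#' @return List with `condition_means` (data frame), `r`, `df`, `p`.
#' @export
motor_adaptation_summary <- function(trials) {
  sel <- trials$condition == "probe" & trials$status == "valid" &
    !is.na(trials$preceding_manipulation_deg)
  d <- trials[sel, ]
  conds <- sort(unique(d$preceding_manipulation_deg))
  if (length(conds) < 3L)
    stop("need at least 3 preceding-manipulation conditions")
  per_subj <- stats::aggregate(
    d[, c("mpd_deg", "ppd_corr_deg")],
    by = list(subject_id = d$subject_id,
              preceding_manipulation_deg = d$preceding_manipulation_deg),
    FUN = mean)
  pop <- stats::aggregate(
    per_subj[, c("mpd_deg", "ppd_corr_deg")],
    by = list(preceding_manipulation_deg =
                per_subj$preceding_manipulation_deg),
    FUN = mean)
  pop <- pop[order(pop$preceding_manipulation_deg), ]
  r <- stats::cor(pop$mpd_deg, pop$ppd_corr_deg)
  df <- nrow(pop) - 2L
  tval <- r * sqrt(df / (1 - r^2))
  list(condition_means = pop, r = r, df = df,
       p = 2 * stats::pt(-abs(tval), df))
}

# subject x level matrix from a long cell table (complete cases enforced)
cells_to_matrix <- function(cells, level_col) {
  lev <- sort(unique(cells[[level_col]]))
  subj <- sort(unique(cells$subject_id))
  m <- matrix(NA_real_, length(subj), length(lev),
              dimnames = list(subj, lev))
  m[cbind(match(cells$subject_id, subj),
          match(cells[[level_col]], lev))] <- cells$value
  if (anyNA(m))
    stop("incomplete subject x ", level_col, " table")
  m
}
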