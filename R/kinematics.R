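#' Extract the outward segment of a pointing trajectory
#'
#' Returns the prefix of the trajectory from the first sample through the
#' sample of maximum radial distance from the origin (the movement start).
#' If the maximum is attained more than once the earliest sample is taken.
#'
#' @param samples Data frame with columns `t_s`, `x_deg`, `y_deg`; timestamps
#'   strictly increasing, at least 3 samples.
#' @return The outward prefix of `samples`.
#' @export
outward_segment <- function(samples) {
  check_samples(samples)
  r <- sqrt(samples$x_deg^2 + samples$y_deg^2)
  if (max(r) <= 0)
    stop("degenerate movement: all samples at the origin")
  peak <- which.max(r)  # which.max returns the first maximum
  samples[seq_len(peak), , drop = FALSE]
}

#' Motor pointing direction from an outward trajectory segment
#'
#' Fits a straight line through the movement starting point (the origin) by
#' orthogonal regression, i.e. the first principal axis of the uncentred
#' second-moment matrix of the position samples, and returns its direction.
#' Orthogonal regression is symmetric in x and y and has no degeneracy for
#' near-vertical movements. The orientation of the fitted axis is resolved
#' toward the half-plane containing the segment endpoint, so the result is
#' the direction the finger moved, in degrees counterclockwise from
#' rightward, within (-180, 180].
#'
#' @param outward_samples Outward trajectory samples (see [outward_segment()]).
#' @return Direction in degrees.
#' @export
fit_pointing_direction <- function(outward_samples) {
  xy <- as.matrix(outward_samples[, c("x_deg", "y_deg")])
  if (nrow(xy) < 2L)
    stop("need at least 2 samples to fit a direction")
  if (max(abs(xy)) == 0)
    stop("zero spatial variance: cannot fit a direction")
  m <- crossprod(xy)
  e <- eigen(m, symmetric = TRUE)
  v <- e$vectors[, 1L]
  endpoint <- xy[nrow(xy), ]
  if (sum(v * endpoint) < 0) v <- -v
  ang <- atan2(v[2L], v[1L]) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

#' Maximum chord deviation of an outward movement
#'
#' Maximum perpendicular distance of any sample from the straight line
#' (chord) connecting the first and last sample of the outward segment.
#' Used to detect pronounced curvature, i.e. online movement corrections.
#'
#' @param outward_samples Outward trajectory samples.
#' @return Deviation in degrees (>= 0).
#' @export
max_chord_deviation <- function(outward_samples) {
  xy <- as.matrix(outward_samples[, c("x_deg", "y_deg")])
  a <- xy[1L, ]
  b <- xy[nrow(xy), ]
  chord <- b - a
  len <- sqrt(sum(chord^2))
  if (len == 0)
    stop("coincident endpoints: chord undefined")
  d <- abs(chord[1L] * (xy[, 2L] - a[2L]) - chord[2L] * (xy[, 1L] - a[1L])) / len
  max(d)
}

#' Peak movement speed
#'
#' Maximum over consecutive sample pairs of the Euclidean displacement
#' divided by the time step. No smoothing is applied: the velocity criterion
#' targets tracker sampling artefacts, which smoothing would hide.
#'
#' @param samples Trajectory samples with strictly increasing `t_s`.
#' @return Peak speed in degrees per second.
#' @export
peak_speed <- function(samples) {
  if (nrow(samples) < 2L) stop("need at least 2 samples")
  dt <- diff(samples$t_s)
  if (any(dt <= 0)) stop("timestamps must be strictly increasing")
  dx <- diff(samples$x_deg)
  dy <- diff(samples$y_deg)
  max(sqrt(dx^2 + dy^2) / dt)
}

#' Kinematic summary of a single trajectory
#'
#' Computes the motor pointing direction, amplitude (maximum radial
#' distance), maximum chord deviation and peak speed of one movement, and
#' classifies it against the validity/exclusion thresholds (without the
#' table-level rules that need trial context, i.e. missing estimates and the
#' probe-discard rule).
#'
#' @param samples Trajectory samples for one movement.
#' @param instructed_amplitude_deg Instructed movement amplitude.
#' @param thresholds See [analysis_thresholds()].
#' @return A list with `mpd`, `amplitude`, `max_chord_deviation`,
#'   `peak_speed` and `status` (one of `"valid"`, `"invalid_amplitude"`,
#'   `"excluded_curvature"`, `"excluded_velocity"`).
#' @export
kinematic_result <- function(samples, instructed_amplitude_deg = 9,
                             thresholds = analysis_thresholds()) {
  out <- outward_segment(samples)
  amp <- max(sqrt(out$x_deg^2 + out$y_deg^2))
  mpd <- fit_pointing_direction(out)
  dev <- max_chord_deviation(out)
  spd <- peak_speed(out)
  status <- if (amp < thresholds$amplitude_validity_fraction *
                  instructed_amplitude_deg) {
    "invalid_amplitude"
  } else if (dev > thresholds$curvature_threshold_deg) {
    "excluded_curvature"
  } else if (spd > thresholds$speed_threshold_deg_s) {
    "excluded_velocity"
  } else {
    "valid"
  }
  list(mpd = mpd, amplitude = amp, max_chord_deviation = dev,
       peak_speed = spd, status = status)
}

#' Kinematic validity and exclusion thresholds
#'
#' @param curvature_threshold_deg Trials whose maximum chord deviation
#'   exceeds this value (strictly) are excluded as likely online corrections.
#' @param speed_threshold_deg_s Trials whose peak speed exceeds this value
#'   (strictly) are excluded as tracker artefacts.
#' @param amplitude_validity_fraction Trials with amplitude below this
#'   fraction of the instructed amplitude are invalid.
#' @param feedback_visibility_amplitude_deg Amplitude above which visual
#'   feedback is shown in feedback trials.
#' @return A list of thresholds.
#' @export
analysis_thresholds <- function(curvature_threshold_deg = 2.25,
                                speed_threshold_deg_s = 120,
                                amplitude_validity_fraction = 0.5,
                                feedback_visibility_amplitude_deg = 4.5) {
  stopifnot(curvature_threshold_deg > 0, speed_threshold_deg_s > 0,
            amplitude_validity_fraction > 0,
            feedback_visibility_amplitude_deg > 0)
  list(curvature_threshold_deg = curvature_threshold_deg,
       speed_threshold_deg_s = speed_threshold_deg_s,
       amplitude_validity_fraction = amplitude_validity_fraction,
       feedback_visibility_amplitude_deg = feedback_visibility_amplitude_deg)
}

#' Assign validity/exclusion statuses to a cohort of trials
#'
#' Applies, in order: amplitude validity (amplitude below half the instructed
#' amplitude), missing perceptual estimate, curvature exclusion (chord
#' deviation strictly above threshold), velocity exclusion (peak speed
#' strictly above threshold); finally every probe trial whose immediately
#' preceding feedback trial is non-valid is discarded
#' (`"discarded_follow"`). When raw trajectory samples are supplied the
#' kinematic quantities (`mpd_deg`, `amplitude_deg`, `max_dev_deg`,
#' `peak_speed_deg_s`) are recomputed from them first, and `ppd_deg` is
#' refreshed as `epd_deg - mpd_deg`.
#'
#' @param trials Trial table (see [read_trials()] for the schema).
#' @param samples Optional long-format samples table covering every trial.
#' @param thresholds See [analysis_thresholds()].
#' @return The trial table with the `status` column (re)assigned.
#' @export
classify_and_filter <- function(trials, samples = NULL,
                                thresholds = analysis_thresholds()) {
  if (!is.null(samples)) {
    key_t <- paste(trials$subject_id, trials$trial_index)
    key_s <- paste(samples$subject_id, samples$trial_index)
    idx <- split(seq_len(nrow(samples)), factor(key_s, levels = key_t))
    miss <- key_t[lengths(idx) == 0L]
    if (length(miss))
      stop("trials without trajectory samples: ", paste(miss, collapse = "; "))
    for (i in seq_len(nrow(trials))) {
      kin <- kinematic_result(samples[idx[[i]], , drop = FALSE],
                              trials$instructed_amplitude_deg[i], thresholds)
      trials$mpd_deg[i] <- kin$mpd
      trials$amplitude_deg[i] <- kin$amplitude
      trials$max_dev_deg[i] <- kin$max_chord_deviation
      trials$peak_speed_deg_s[i] <- kin$peak_speed
    }
    trials$ppd_deg <- trials$epd_deg - trials$mpd_deg
  }
  status <- ifelse(
    trials$amplitude_deg < thresholds$amplitude_validity_fraction *
      trials$instructed_amplitude_deg, "invalid_amplitude",
    ifelse(is.na(trials$epd_deg), "invalid_no_estimate",
      ifelse(trials$max_dev_deg > thresholds$curvature_threshold_deg,
             "excluded_curvature",
        ifelse(trials$peak_speed_deg_s > thresholds$speed_threshold_deg_s,
               "excluded_velocity", "valid"))))
  # probe trials are interpreted via the preceding feedback trial; discard
  # them when that trial cannot be evaluated (computed last)
  ord <- order(trials$subject_id, trials$trial_index)
  st <- status[ord]
  tr <- trials[ord, ]
  prev_same_subject <- c(FALSE, tr$subject_id[-1] == tr$subject_id[-nrow(tr)])
  prev_status <- c(NA_character_, st[-length(st)])
  discard <- tr$condition == "probe" & st == "valid" &
    (!prev_same_subject | prev_status != "valid")
  st[discard] <- "discarded_follow"
  status[ord] <- st
  trials$status <- status
  trials
}

check_samples <- function(samples) {
  stopifnot(is.data.frame(samples),
            all(c("t_s", "x_deg", "y_deg") %in% names(samples)))
  if (nrow(samples) < 3L) stop("need at least 3 trajectory samples")
  if (!all(is.finite(samples$x_deg)) || !all(is.finite(samples$y_deg)))
    stop("non-finite trajectory coordinates")
  if (any(diff(samples$t_s) <= 0))
    stop("timestamps must be strictly increasing")
  invisible(samples)
}
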