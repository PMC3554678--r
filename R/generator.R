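#' Draw one feedback manipulation angle
#'
#' Samples a signed rotation angle from the discrete uniform distribution
#' over `params$manipulation_set` (by default 0, +-5, +-10, +-20, +-40
#' degrees; positive = counterclockwise). Uses the current R RNG state, so
#' wrap calls in `set.seed()` for reproducibility.
#'
#' @param params A [generator_params()] object.
#' @return A signed angle in degrees.
#' @export
draw_manipulation <- function(params) {
  s <- params$manipulation_set
  if (length(s) == 1L) return(s)
  sample(s, 1L)
}

#' Simulate one centre-out pointing trajectory
#'
#' Generates timed 2-D fingertip positions for one outward-and-back pointing
#' movement along direction `mpd`: a minimum-jerk radial profile out to the
#' movement amplitude with a smooth, sinusoidal lateral bow (zero at both
#' ends, so the bow magnitude equals the maximum chord deviation), followed
#' by a straight partial return. Timestamps increase at `sample_rate_hz`.
#'
#' @param mpd Intended movement direction, degrees counterclockwise from
#'   rightward.
#' @param params A [generator_params()] object.
#' @param amplitude_deg Movement amplitude; defaults to the instructed
#'   amplitude plus a small positive overshoot so feedback is always shown.
#' @param curvature_deg Signed lateral bow magnitude; defaults to a draw
#'   from Normal(0, `curvature_noise_sd_deg`).
#' @return Data frame with columns `t_s`, `x_deg`, `y_deg`.
#' @export
simulate_trajectory <- function(mpd, params,
                                amplitude_deg = NULL,
                                curvature_deg = NULL) {
  stopifnot(is.finite(mpd))
  if (is.null(amplitude_deg))
    amplitude_deg <- params$instructed_amplitude_deg + abs(stats::rnorm(1, 0, 0.25))
  if (is.null(curvature_deg))
    curvature_deg <- stats::rnorm(1, 0, params$curvature_noise_sd_deg)
  n <- params$n_traj_samples
  n_out <- max(4L, ceiling(2 * n / 3))
  n_back <- n - n_out
  # minimum-jerk position profile on [0, 1]
  minjerk <- function(tau) 10 * tau^3 - 15 * tau^4 + 6 * tau^5
  s_out <- minjerk(seq(0, 1, length.out = n_out))
  r <- amplitude_deg * s_out
  lat <- curvature_deg * sin(pi * s_out)
  if (n_back > 0L) {
    s_back <- minjerk(seq(0, 1, length.out = n_back + 1L))[-1L]
    r <- c(r, amplitude_deg * (1 - 0.6 * s_back))
    lat <- c(lat, rep(0, n_back))
  }
  theta <- mpd * pi / 180
  u <- c(cos(theta), sin(theta))       # along movement direction
  v <- c(-sin(theta), cos(theta))      # perpendicular, counterclockwise
  data.frame(
    t_s = (seq_along(r) - 1L) / params$sample_rate_hz,
    x_deg = r * u[1L] + lat * v[1L],
    y_deg = r * u[2L] + lat * v[2L]
  )
}

#' Simulate one feedback trial
#'
#' The subject freely chooses a motor direction (uniform on
#' `mpd_range_deg`); the visual feedback is rotated by `manipulation`
#' degrees. The perceived pointing direction mixes the rotation according to
#' the attribution-weight profile: PPD = offset + w(|m|) * m + noise. The
#' realised internally attributed error component (w(|m|) * m + noise) is
#' carried forward in the returned state, where the next probe trial reads it.
#'
#' @param manipulation Signed rotation in degrees; its absolute value must be
#'   0 or a key of the weight profile.
#' @param params A [generator_params()] object.
#' @return List with elements `mpd_target`, `ppd` (perceived pointing
#'   direction including offset), and `state` (manipulation, realised
#'   attributed component, and feedback PPD for the following probe trial).
#' @export
simulate_feedback_trial <- function(manipulation, params) {
  amount <- abs(manipulation)
  w <- weight_of(params, amount)  # rejects unknown amounts
  mpd_target <- stats::runif(1, params$mpd_range_deg[1], params$mpd_range_deg[2])
  attributed <- w * manipulation +
    stats::rnorm(1, 0, params$perceptual_noise_sd_deg)
  ppd <- params$offset_fb_deg + attributed
  list(mpd_target = mpd_target, ppd = ppd,
       state = list(manipulation = manipulation,
                    attributed = attributed,
                    ppd_fb = ppd))
}

#' Simulate one perceptual probe trial
#'
#' No visual feedback is given; the perceived pointing direction reflects the
#' internal sensory prediction, recalibrated by the preceding feedback
#' trial. In `"attributed"` coupling mode the probe PPD is proportional to
#' the realised internally attributed error component of the preceding trial
#' (coefficient g/w for that amount), gated by the error deadzone: amounts
#' less than or equal to `deadzone_deg` induce no recalibration. In
#' `"uniform"` mode the probe PPD is `beta_uniform` times the preceding
#' feedback PPD for all trials. The freely chosen motor direction is shifted
#' opposite to the recalibrated visual consequence by
#' `motor_adapt_gain * g(|m|) * m` (motor adaptation).
#'
#' @param prev_state State list emitted by [simulate_feedback_trial()].
#' @param params A [generator_params()] object.
#' @return List with `mpd_target` and `ppd`.
#' @export
simulate_probe_trial <- function(prev_state, params) {
  if (is.null(prev_state))
    stop("probe trial requires the preceding feedback trial's state")
  m <- prev_state$manipulation
  amount <- abs(m)
  g <- gain_of(params, amount)
  noise <- stats::rnorm(1, 0, params$perceptual_noise_sd_deg)
  recal <- if (params$coupling_mode == "attributed") {
    if (amount > params$deadzone_deg && g > 0) {
      (g / weight_of(params, amount)) * prev_state$attributed
    } else 0
  } else {
    params$beta_uniform * prev_state$ppd_fb
  }
  ppd <- params$offset_pp_deg + recal + noise
  adapt <- params$motor_adapt_gain * g * m
  mpd_target <- stats::runif(1, params$mpd_range_deg[1],
                             params$mpd_range_deg[2]) - adapt
  list(mpd_target = mpd_target, ppd = ppd)
}

#' Generate a synthetic cohort of alternating feedback/probe trials
#'
#' For each subject, simulates `n_pairs` strictly alternating
#' feedback-then-probe trial pairs, each with a raw fingertip trajectory.
#' The motor pointing direction recorded for each trial is the one obtained
#' by fitting the generated trajectory (so the analysis chain and the
#' generative chain agree exactly), and the estimated pointing direction is
#' EPD = MPD + PPD. Trial statuses are pre-assigned with the default
#' thresholds; with `invalid_rate > 0` a corresponding fraction of trials
#' violates one of the rules (short amplitude, pronounced curvature,
#' velocity artefact, or missing estimate) to exercise the filters.
#' The output is a deterministic function of `params` (including the seed).
#'
#' @param params A [generator_params()] object.
#' @return An object of class `recalib_cohort`: a list with `trials` (trial
#'   table in the external schema), `samples` (long-format trajectory
#'   samples) and `params`.
#' @export
generate_cohort <- function(params = generator_params()) {
  validate_params(params)
  set.seed(params$seed)
  thresholds <- analysis_thresholds()
  n_trials <- 2L * params$n_pairs
  trial_rows <- vector("list", params$n_subjects * n_trials)
  sample_rows <- vector("list", params$n_subjects * n_trials)
  k <- 0L
  for (subj in seq_len(params$n_subjects)) {
    sid <- sprintf("S%02d", subj)
    state <- NULL
    for (pair in seq_len(params$n_pairs)) {
      for (cond in c("feedback", "probe")) {
        if (cond == "feedback") {
          m <- draw_manipulation(params)
          sim <- simulate_feedback_trial(m, params)
          state <- sim$state
        } else {
          sim <- simulate_probe_trial(state, params)
        }
        viol <- if (params$invalid_rate > 0 &&
                    stats::runif(1) < params$invalid_rate) {
          sample(c("amplitude", "curvature", "velocity", "no_estimate"), 1L)
        } else "none"
        traj <- simulate_trajectory(
          sim$mpd_target, params,
          amplitude_deg = if (viol == "amplitude")
            0.4 * params$instructed_amplitude_deg else NULL,
          curvature_deg = if (viol == "curvature")
            sample(c(-1, 1), 1L) * 3.5 else NULL)
        if (viol == "velocity") {
          # single-sample radial jump, emulating a tracker artefact
          i <- ceiling(nrow(traj) / 3)
          ru <- traj[i, c("x_deg", "y_deg")] /
            sqrt(sum(traj[i, c("x_deg", "y_deg")]^2))
          traj$x_deg[i] <- traj$x_deg[i] + 3 * ru[[1L]]
          traj$y_deg[i] <- traj$y_deg[i] + 3 * ru[[2L]]
        }
        kin <- kinematic_result(traj, params$instructed_amplitude_deg,
                                thresholds)
        epd <- if (viol == "no_estimate") NA_real_ else kin$mpd + sim$ppd
        k <- k + 1L
        idx <- 2L * (pair - 1L) + if (cond == "feedback") 1L else 2L
        trial_rows[[k]] <- data.frame(
          subject_id = sid,
          trial_index = idx,
          condition = cond,
          manipulation_deg = if (cond == "feedback")
            state$manipulation else NA_real_,
          preceding_manipulation_deg = if (cond == "probe")
            state$manipulation else NA_real_,
          instructed_amplitude_deg = params$instructed_amplitude_deg,
          epd_deg = epd,
          mpd_deg = kin$mpd,
          ppd_deg = epd - kin$mpd,
          amplitude_deg = kin$amplitude,
          max_dev_deg = kin$max_chord_deviation,
          peak_speed_deg_s = kin$peak_speed,
          status = "valid"
        )
        sample_rows[[k]] <- data.frame(
          subject_id = sid, trial_index = idx,
          t_s = traj$t_s, x_deg = traj$x_deg, y_deg = traj$y_deg)
      }
    }
  }
  trials <- do.call(rbind, trial_rows)
  samples <- do.call(rbind, sample_rows)
  rownames(trials) <- rownames(samples) <- NULL
  trials <- classify_and_filter(trials, thresholds = thresholds)
  structure(list(trials = trials, samples = samples, params = params),
            class = "recalib_cohort")
}

#' @export
print.recalib_cohort <- function(x, ...) {
  cat("<recalib_cohort>\n")
  cat(sprintf("  %d subjects, %d trials (%d feedback + %d probe)\n",
              length(unique(x$trials$subject_id)), nrow(x$trials),
              sum(x$trials$condition == "feedback"),
              sum(x$trials$condition == "probe")))
  acct <- table(x$trials$status)
  cat("  status:", paste(names(acct), acct, sep = "=", collapse = ", "), "\n")
  invisible(x)
}
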