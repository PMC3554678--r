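#' Generator parameters for a synthetic pointing cohort
#'
#' Bundles every knob of the synthetic-cohort generator: cohort dimensions,
#' the discrete distribution of feedback rotations, the attribution-weight
#' and recalibration-gain profiles, the error deadzone, probe-trial coupling,
#' motor adaptation, constant perceptual offsets, noise magnitudes and the
#' trajectory geometry. Defaults reproduce the reference experimental
#' conditions: 11 subjects, 180 alternating feedback/probe pairs each,
#' rotations drawn uniformly from {0, +-5, +-10, +-20, +-40} degrees,
#' attribution weights 0.54/0.57/0.38/0.19 and recalibration gains
#' 0/0.20/0.14/0.07 at 5/10/20/40 degrees, a 5 degree deadzone, and freely
#' chosen movement directions uniform on [10, 70] degrees.
#'
#' @param n_subjects Number of simulated subjects.
#' @param n_pairs Number of feedback+probe trial pairs per subject.
#' @param manipulation_set Signed feedback rotations (degrees) sampled with
#'   equal probability; 0 denotes veridical feedback.
#' @param attribution_weight_by_amount Named numeric vector mapping the
#'   absolute amount of manipulation (degrees, as names) to the relative
#'   weight w of visual information, i.e. the internally attributed share of
#'   the visual prediction error. All weights must lie in [0, 1].
#' @param recal_gain_by_amount Named numeric vector mapping amount to the
#'   relative recalibration gain g (>= 0) of the internal sensory prediction.
#' @param deadzone_deg Error deadzone: amounts of manipulation less than or
#'   equal to this value induce no recalibration in the following probe trial.
#' @param coupling_mode `"attributed"` couples each probe trial's perceived
#'   direction to the realised internally attributed error component of the
#'   preceding feedback trial with coefficient g/w, so that both per-amount
#'   condition means and within-amount trial-by-trial correlations arise from
#'   one mechanism; `"uniform"` instead sets the probe percept to
#'   `beta_uniform` times the preceding feedback-trial percept for all trials
#'   (used for regression-slope recovery).
#' @param beta_uniform Trial-by-trial coupling coefficient in uniform mode.
#' @param motor_adapt_gain Scale of motor adaptation: probe-trial movement
#'   directions are shifted by minus this gain times g(|m|) times the
#'   preceding manipulation, opposing the recalibrated visual consequence.
#' @param offset_fb_deg,offset_pp_deg Constant perceptual offsets (degrees)
#'   added to the perceived pointing direction in feedback and probe trials;
#'   exercised by the offset-correction stage.
#' @param perceptual_noise_sd_deg SD (degrees) of the Gaussian trial-by-trial
#'   noise on perceptual estimates, homoscedastic across conditions.
#' @param mpd_range_deg Interval (degrees) from which freely chosen motor
#'   pointing directions are drawn uniformly.
#' @param instructed_amplitude_deg Instructed movement amplitude (degrees of
#'   visual angle).
#' @param curvature_noise_sd_deg SD (degrees) of the smooth lateral bowing of
#'   simulated trajectories; controls the maximum chord deviation.
#' @param n_traj_samples Number of position samples per simulated trajectory.
#' @param sample_rate_hz Sampling rate of the simulated tracker.
#' @param invalid_rate Probability that a simulated trial violates one of the
#'   validity/exclusion rules (short amplitude, pronounced curvature,
#'   velocity artefact, or missing estimate), used to exercise the filters.
#'   Default 0: clean cohort.
#' @param seed Integer seed; a cohort is a deterministic function of the
#'   parameter set including the seed.
#'
#' @return An object of class `recalib_params` (a validated list).
#' @seealso [generate_cohort()]
#' @export
generator_params <- function(n_subjects = 11,
                             n_pairs = 180,
                             manipulation_set = c(0, 5, 10, 20, 40,
                                                  -5, -10, -20, -40),
                             attribution_weight_by_amount =
                               c("5" = 0.54, "10" = 0.57,
                                 "20" = 0.38, "40" = 0.19),
                             recal_gain_by_amount =
                               c("5" = 0, "10" = 0.20,
                                 "20" = 0.14, "40" = 0.07),
                             deadzone_deg = 5,
                             coupling_mode = c("attributed", "uniform"),
                             beta_uniform = 0.219,
                             motor_adapt_gain = 1,
                             offset_fb_deg = 0,
                             offset_pp_deg = 0,
                             perceptual_noise_sd_deg = 4,
                             mpd_range_deg = c(10, 70),
                             instructed_amplitude_deg = 9,
                             curvature_noise_sd_deg = 0.5,
                             n_traj_samples = 48,
                             sample_rate_hz = 60,
                             invalid_rate = 0,
                             seed = 1L) {
  coupling_mode <- match.arg(coupling_mode)
  p <- list(
    n_subjects = as.integer(n_subjects),
    n_pairs = as.integer(n_pairs),
    manipulation_set = as.numeric(manipulation_set),
    attribution_weight_by_amount = attribution_weight_by_amount,
    recal_gain_by_amount = recal_gain_by_amount,
    deadzone_deg = deadzone_deg,
    coupling_mode = coupling_mode,
    beta_uniform = beta_uniform,
    motor_adapt_gain = motor_adapt_gain,
    offset_fb_deg = offset_fb_deg,
    offset_pp_deg = offset_pp_deg,
    perceptual_noise_sd_deg = perceptual_noise_sd_deg,
    mpd_range_deg = as.numeric(mpd_range_deg),
    instructed_amplitude_deg = instructed_amplitude_deg,
    curvature_noise_sd_deg = curvature_noise_sd_deg,
    n_traj_samples = as.integer(n_traj_samples),
    sample_rate_hz = sample_rate_hz,
    invalid_rate = invalid_rate,
    seed = as.integer(seed)
  )
  class(p) <- "recalib_params"
  validate_params(p)
  p
}

validate_params <- function(p) {
  stopifnot(
    p$n_subjects >= 1L,
    p$n_pairs >= 1L,
    length(p$manipulation_set) >= 1L,
    all(is.finite(p$manipulation_set))
  )
  amounts <- setdiff(unique(abs(p$manipulation_set)), 0)
  w <- p$attribution_weight_by_amount
  g <- p$recal_gain_by_amount
  if (!all(as.character(amounts) %in% names(w)))
    stop("attribution_weight_by_amount must cover every non-zero |manipulation|")
  if (!all(as.character(amounts) %in% names(g)))
    stop("recal_gain_by_amount must cover every non-zero |manipulation|")
  if (any(w < 0 | w > 1)) stop("attribution weights must lie in [0, 1]")
  if (any(g < 0)) stop("recalibration gains must be >= 0")
  # probe coupling divides by w; only needed where the gain is active
  active <- amounts[amounts > p$deadzone_deg]
  if (p$coupling_mode == "attributed" &&
      any(w[as.character(active)] <= 0 & g[as.character(active)] > 0))
    stop("g/w undefined: zero weight with positive gain above the deadzone")
  if (!(p$deadzone_deg == 0 || p$deadzone_deg %in% abs(p$manipulation_set)))
    stop("deadzone_deg must be 0 or one of the manipulation amounts")
  stopifnot(
    p$perceptual_noise_sd_deg >= 0,
    p$curvature_noise_sd_deg >= 0,
    length(p$mpd_range_deg) == 2L,
    p$mpd_range_deg[1] <= p$mpd_range_deg[2],
    p$instructed_amplitude_deg > 0,
    p$n_traj_samples >= 6L,
    p$sample_rate_hz > 0,
    p$invalid_rate >= 0, p$invalid_rate <= 1,
    p$motor_adapt_gain >= 0,
    is.finite(p$beta_uniform)
  )
  invisible(p)
}

#' @export
print.recalib_params <- function(x, ...) {
  cat("<recalib_params>\n")
  cat(sprintf("  cohort: %d subjects x %d feedback/probe pairs (seed %d)\n",
              x$n_subjects, x$n_pairs, x$seed))
  cat("  manipulations (deg):", paste(sort(x$manipulation_set), collapse = ", "),
      "\n")
  cat("  w by amount:",
      paste(sprintf("%s:%.2f", names(x$attribution_weight_by_amount),
                    x$attribution_weight_by_amount), collapse = " "), "\n")
  cat("  g by amount:",
      paste(sprintf("%s:%.2f", names(x$recal_gain_by_amount),
                    x$recal_gain_by_amount), collapse = " "), "\n")
  cat(sprintf("  deadzone %g deg; coupling %s; noise sd %g deg\n",
              x$deadzone_deg, x$coupling_mode, x$perceptual_noise_sd_deg))
  invisible(x)
}

# profile lookups; reject unknown amounts so schema errors surface early
weight_of <- function(params, amount) {
  if (amount == 0) return(0)
  key <- as.character(amount)
  w <- params$attribution_weight_by_amount[key]
  if (is.na(w)) stop("unknown amount of manipulation: ", amount)
  unname(w)
}

gain_of <- function(params, amount) {
  if (amount == 0) return(0)
  key <- as.character(amount)
  g <- params$recal_gain_by_amount[key]
  if (is.na(g)) stop("unknown amount of manipulation: ", amount)
  unname(g)
}
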