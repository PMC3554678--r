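# lazily computed fixtures shared across test files
.fixtures <- new.env(parent = emptyenv())

# small, fast cohort for unit tests
small_params <- function(...) {
  generator_params(n_subjects = 4, n_pairs = 45, seed = 11, ...)
}

small_report <- function() {
  if (is.null(.fixtures$small_report))
    .fixtures$small_report <- run_pipeline(pipeline_config(small_params()))
  .fixtures$small_report
}

# full-scale reference cohort (default generator parameters, both the
# attribution-weight and recalibration-gain profiles active)
reference_report <- function() {
  if (is.null(.fixtures$reference_report))
    .fixtures$reference_report <-
      run_pipeline(pipeline_config(generator_params(seed = 42)))
  .fixtures$reference_report
}

# a clean trial-table row for constructed filter scenarios
make_trial <- function(subject_id, trial_index, condition,
                       manipulation = NA, preceding = NA,
                       epd = 50, mpd = 45, amplitude = 9,
                       max_dev = 0.5, peak_speed = 30,
                       instructed = 9) {
  data.frame(subject_id = subject_id, trial_index = trial_index,
             condition = condition,
             manipulation_deg = manipulation,
             preceding_manipulation_deg = preceding,
             instructed_amplitude_deg = instructed,
             epd_deg = epd, mpd_deg = mpd, ppd_deg = epd - mpd,
             amplitude_deg = amplitude, max_dev_deg = max_dev,
             peak_speed_deg_s = peak_speed, status = "valid")
}
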