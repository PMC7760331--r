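# In-code fixtures: hand-built traces and tiny cohort configs.

# a pupil trace on a uniform grid starting at t0 (seconds)
make_trace <- function(pupil, rate = 250, t0 = 0, gaze_x = NULL,
                       gaze_y = NULL, valid = NULL, condition = "reward") {
  n <- length(pupil)
  structure(data.frame(
    time = t0 + (seq_len(n) - 1) / rate,
    pupil = pupil,
    gaze_x = gaze_x %||% rep(960, n),
    gaze_y = gaze_y %||% rep(540, n),
    valid = valid %||% !is.na(pupil)),
    class = c("pupil_trace", "data.frame"),
    condition = condition, sampling_rate = rate)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

config_with <- function(defaults, overrides) {
  do.call(cohort_config, utils::modifyList(defaults, overrides))
}

# small, quiet cohort for structural tests
tiny_config <- function(...) {
  config_with(list(n_control = 3, n_depressed = 4, seed = 42,
                   missing_run_prob = 0), list(...))
}

# clean config: no artifacts, no noise (ground truth passes through exactly)
clean_config <- function(...) {
  config_with(list(n_control = 2, n_depressed = 2, seed = 7, noise_sd = 0,
                   blink_rate = 0, gaze_excursion_prob = 0,
                   missing_run_prob = 0), list(...))
}
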