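# Configuration for the synthetic reward-anticipation pupillometry cohort.

#' Cohort simulation configuration
#'
#' Parameters of the synthetic cohort generator. Defaults emulate the study
#' conditions of the reward-anticipation paradigm: three isoluminant cue
#' conditions presented for 6 s each, ten trials per condition, 250 Hz
#' sampling, cohort of 41 depressed participants and 25 controls, an adaptive
#' response deadline holding reward-trial success near 50%, and a programmed
#' correlation of about -0.5 between reward-anticipatory pupil dilation and
#' depressive symptom load (and between dilation and response time).
#'
#' @param n_control,n_depressed subjects per group (>= 1).
#' @param trials_per_condition trials per cue condition (default 10).
#' @param sampling_rate eye-tracker sampling rate in Hz (default 250).
#' @param anticipation_duration cue/anticipation window length in seconds
#'   (default 6).
#' @param baseline_duration pre-cue baseline recorded per trial, seconds
#'   (default 1).
#' @param target_corr_dilation_symptoms programmed population correlation
#'   between the subject's reward dilation slope and symptom count, strictly
#'   inside (-1, 1).
#' @param target_corr_dilation_rt programmed correlation between reward
#'   dilation slope and median response time, strictly inside (-1, 1).
#' @param blink_rate blink events per minute.
#' @param blink_duration_mean mean blink duration in seconds.
#' @param gaze_excursion_prob probability per trial of a sustained gaze
#'   excursion outside the fixation window.
#' @param missing_run_prob probability that a subject's run receives enough
#'   eye-closure artifact to exceed the run-level missingness threshold.
#' @param seed integer RNG seed; identical (config, seed) gives
#'   byte-identical cohorts.
#' @param slope_reward_mean,slope_reward_sd population mean/SD of the reward
#'   condition dilation slope (z-units per second).
#' @param slope_neutral_mean,slope_neutral_sd same for the neutral condition.
#' @param slope_control_mean,slope_control_sd same for the no-response
#'   control condition (negative mean: pupil constriction).
#' @param noise_sd stationary SD of the additive AR(1) pupil noise
#'   (z-units).
#' @param noise_ar1 lag-1 autocorrelation of the pupil noise at the sample
#'   level.
#' @param pupil_units_per_z scale from z-units to raw recording units.
#' @param baseline_mean,baseline_between_sd mean and between-subject SD of
#'   the raw baseline pupil level (recording units).
#' @param rt_mean,rt_sd_between,rt_sd_within response-time model: subject
#'   mean level, between-subject SD, within-subject (trial) SD, seconds.
#' @param deadline_initial,deadline_step staircase parameters of the
#'   adaptive response deadline, seconds.
#' @param gaze_wander_sd SD of the fixational gaze wander (pixels).
#' @param gaze_excursion_offset displacement of gaze excursions (pixels).
#' @param gaze_excursion_duration length-2 range of excursion durations
#'   (seconds).
#' @return an object of class `cohort_config` (validated named list).
#' @export
cohort_config <- function(n_control = 25L, n_depressed = 41L,
                          trials_per_condition = 10L,
                          sampling_rate = 250,
                          anticipation_duration = 6,
                          baseline_duration = 1,
                          target_corr_dilation_symptoms = -0.5,
                          target_corr_dilation_rt = -0.5,
                          blink_rate = 15,
                          blink_duration_mean = 0.2,
                          gaze_excursion_prob = 0.05,
                          missing_run_prob = 0.1,
                          seed = 1L,
                          slope_reward_mean = 0.25, slope_reward_sd = 0.08,
                          slope_neutral_mean = 0.12, slope_neutral_sd = 0.05,
                          slope_control_mean = -0.15, slope_control_sd = 0.03,
                          noise_sd = 0.1, noise_ar1 = 0.98,
                          pupil_units_per_z = 400,
                          baseline_mean = 4000, baseline_between_sd = 200,
                          rt_mean = 0.45, rt_sd_between = 0.08,
                          rt_sd_within = 0.08,
                          deadline_initial = 0.5, deadline_step = 0.02,
                          gaze_wander_sd = 10,
                          gaze_excursion_offset = 400,
                          gaze_excursion_duration = c(0.5, 2)) {
  cfg <- as.list(environment())
  counts <- c("n_control", "n_depressed", "trials_per_condition")
  for (nm in counts)
    if (cfg[[nm]] < 1 || cfg[[nm]] != round(cfg[[nm]]))
      stop("cohort_config: ", nm, " must be a count >= 1")
  durs <- c("sampling_rate", "anticipation_duration", "baseline_duration",
            "blink_duration_mean", "deadline_initial", "deadline_step")
  for (nm in durs)
    if (cfg[[nm]] <= 0) stop("cohort_config: ", nm, " must be > 0")
  for (nm in c("target_corr_dilation_symptoms", "target_corr_dilation_rt"))
    if (abs(cfg[[nm]]) >= 1)
      stop("cohort_config: ", nm, " must be strictly inside (-1, 1)")
  for (nm in c("gaze_excursion_prob", "missing_run_prob"))
    if (cfg[[nm]] < 0 || cfg[[nm]] > 1)
      stop("cohort_config: ", nm, " must be a probability in [0, 1]")
  if (cfg$blink_rate < 0) stop("cohort_config: blink_rate must be >= 0")
  if (cfg$noise_sd < 0) stop("cohort_config: noise_sd must be >= 0")
  if (abs(cfg$noise_ar1) >= 1)
    stop("cohort_config: noise_ar1 must be strictly inside (-1, 1)")
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "cohort_config")
}

#' @export
print.cohort_config <- function(x, ...) {
  cat(sprintf(paste0(
    "cohort_config: %d controls + %d depressed, %d trials/condition @ %g Hz\n",
    "  anticipation %g s, baseline %g s; target corr (symptoms, RT) = (%g, %g)\n",
    "  blink rate %g/min, gaze excursion p = %g, run-missing p = %g, seed %d\n"),
    x$n_control, x$n_depressed, x$trials_per_condition, x$sampling_rate,
    x$anticipation_duration, x$baseline_duration,
    x$target_corr_dilation_symptoms, x$target_corr_dilation_rt,
    x$blink_rate, x$gaze_excursion_prob, x$missing_run_prob, x$seed))
  invisible(x)
}

#' Read a cohort configuration from a YAML file
#'
#' Keys mirror the arguments of [cohort_config()]; unknown keys are an
#' error, missing keys take the defaults.
#'
#' @param path path to a YAML config file.
#' @return a `cohort_config`.
#' @export
read_cohort_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(cohort_config))
  bad <- setdiff(names(vals), known)
  if (length(bad))
    stop("read_cohort_config: unknown key(s): ", paste(bad, collapse = ", "))
  do.call(cohort_config, vals)
}

#' Write a cohort configuration to a YAML file
#'
#' @param config a `cohort_config`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_cohort_config <- function(config, path) {
  stopifnot(inherits(config, "cohort_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

# evaluate an expression under a private RNG stream, restoring global state
with_local_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
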