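# Synthetic cohort generator: latent Gaussian copula for the clinical
# scores, condition-ordered dilation slopes, AR(1) pupil noise, blink and
# gaze artifacts, adaptive response deadline.

# Group-conditional symptom-count distributions (DSM-style count 0-9).
# Controls report at most 3 symptoms; in the depressed group about 56%
# report five or more (the acute subgroup).
symptom_pmf <- list(
  control = c(`0` = 0.45, `1` = 0.27, `2` = 0.18, `3` = 0.10),
  depressed = c(`0` = 0.03, `1` = 0.04, `2` = 0.06, `3` = 0.12, `4` = 0.19,
                `5` = 0.20, `6` = 0.16, `7` = 0.11, `8` = 0.06, `9` = 0.03))

# Moments of a discretised standard normal: count k on Z in [t_k, t_{k+1})
# where t = qnorm(cumsum(pmf)). Returns mean, variance and cov(count, Z),
# all in closed form; used to calibrate the copula correlation analytically.
discretisation_moments <- function(pmf) {
  k <- as.numeric(names(pmf))
  t <- stats::qnorm(c(0, cumsum(pmf)))
  phi <- stats::dnorm(t)
  phi[!is.finite(t)] <- 0
  mu <- sum(k * pmf)
  list(mean = mu, var = sum(k^2 * pmf) - mu^2,
       cov_z = sum(k * (phi[-length(phi)] - phi[-1])))
}

# Latent copula correlations needed to realise the target Pearson
# correlations after symptom-count discretisation and RT median noise.
calibrate_copula <- function(config) {
  w <- c(control = config$n_control, depressed = config$n_depressed)
  w <- w / sum(w)
  mom <- lapply(symptom_pmf, discretisation_moments)
  mu_bar <- sum(w * vapply(mom, `[[`, numeric(1), "mean"))
  var_count <- sum(w * vapply(mom, `[[`, numeric(1), "var")) +
    sum(w * (vapply(mom, `[[`, numeric(1), "mean") - mu_bar)^2)
  cov_z <- sum(w * vapply(mom, `[[`, numeric(1), "cov_z"))
  # corr(slope, count) = rho_ds * cov_z / sd(count); solve for rho_ds
  rho_ds <- config$target_corr_dilation_symptoms * sqrt(var_count) / cov_z
  # median of m iid normal trial RTs: var ~ (pi/2) * sd_within^2 / m
  m <- config$trials_per_condition
  med_var <- (pi / 2) * config$rt_sd_within^2 / m
  lambda_rt <- config$rt_sd_between /
    sqrt(config$rt_sd_between^2 + med_var)
  rho_dr <- config$target_corr_dilation_rt / lambda_rt
  if (abs(rho_ds) >= 1 || abs(rho_dr) >= 1)
    stop("generate_cohort: infeasible configuration; the requested target ",
         "correlation cannot be realised after discretisation/noise ",
         "attenuation (required latent correlation outside (-1, 1))")
  # conditional independence of symptoms and RT given the arousal trait
  cm <- diag(3)
  cm[1, 2] <- cm[2, 1] <- rho_ds
  cm[1, 3] <- cm[3, 1] <- rho_dr
  cm[2, 3] <- cm[3, 2] <- rho_ds * rho_dr
  if (min(eigen(cm, symmetric = TRUE, only.values = TRUE)$values) < -1e-10)
    stop("generate_cohort: infeasible configuration; latent correlation ",
         "matrix is not positive semi-definite")
  dimnames(cm) <- rep(list(c("dilation", "symptoms", "rt")), 2)
  cm
}

map_symptom_count <- function(z, group) {
  pmf <- symptom_pmf[[group]]
  thr <- stats::qnorm(cumsum(pmf))
  as.numeric(names(pmf))[findInterval(z, thr[-length(thr)]) + 1L]
}

#' Generate a synthetic cohort
#'
#' Draws per-subject latent traits (arousal, symptom load, response speed)
#' from a Gaussian copula whose correlations are calibrated analytically so
#' that, in expectation, the Pearson correlation between the subject's
#' ground-truth reward dilation slope and the (discretised) symptom count
#' equals `target_corr_dilation_symptoms` (and likewise for median RT).
#' Clinical scores, per-trial response times with the adaptive deadline, and
#' artifact-laden pupil/gaze traces are generated per subject.
#'
#' @param config a [cohort_config()].
#' @param generate_traces if `FALSE`, only clinical scores and ground truth
#'   are produced (fast path for calibration checks at large n).
#' @return an object of class `cohort`: list with `config`, `clinical`
#'   (one row per subject), `subjects` (list of subject datasets, each with
#'   `traces` and a `trials` table), and `ground_truth` (latent traits,
#'   per-condition slopes, the latent correlation matrix, and the per-trace
#'   artifact masks).
#' @export
generate_cohort <- function(config, generate_traces = TRUE) {
  stopifnot(inherits(config, "cohort_config"))
  latent_corr <- calibrate_copula(config)
  with_local_seed(config$seed, {
    n <- config$n_control + config$n_depressed
    group <- rep(c("control", "depressed"),
                 c(config$n_control, config$n_depressed))
    z <- MASS::mvrnorm(n, rep(0, 3), latent_corr)
    colnames(z) <- c("dilation", "symptoms", "rt")

    symptom_count <- vapply(seq_len(n), function(i)
      map_symptom_count(z[i, "symptoms"], group[i]), numeric(1))
    symptom_impact <- pmin(10, pmax(0, round(symptom_count +
                                               stats::rnorm(n, 0, 1))))
    anhedonia <- round(pmax(0, 0.35 * symptom_count +
                              stats::rnorm(n, 0.3, 0.4)), 2)
    age <- round(ifelse(group == "control",
                        pmin(61, pmax(20, stats::rnorm(n, 32, 10))),
                        pmin(64, pmax(19, stats::rnorm(n, 36, 13)))))
    sex <- ifelse(stats::runif(n) < ifelse(group == "control", 12/25, 27/41),
                  "female", "male")
    clinical <- data.frame(
      subject = sprintf("sub-%03d", seq_len(n)),
      group = group, symptom_count = symptom_count,
      symptom_impact = symptom_impact, anhedonia = anhedonia,
      age = age, sex = sex, acute_flag = symptom_count >= 5,
      stringsAsFactors = FALSE)

    traits <- data.frame(
      subject = clinical$subject,
      z_dilation = z[, "dilation"], z_symptoms = z[, "symptoms"],
      z_rt = z[, "rt"],
      slope_reward = config$slope_reward_mean +
        config$slope_reward_sd * z[, "dilation"],
      slope_neutral = config$slope_neutral_mean +
        config$slope_neutral_sd * z[, "dilation"],
      slope_control = config$slope_control_mean +
        config$slope_control_sd * z[, "dilation"],
      baseline_level = config$baseline_mean +
        config$baseline_between_sd * stats::rnorm(n),
      rt_level = config$rt_mean + config$rt_sd_between * z[, "rt"],
      fixation_x = 960 + stats::rnorm(n, 0, 20),
      fixation_y = 540 + stats::rnorm(n, 0, 20),
      stringsAsFactors = FALSE)

    force_missing <- stats::runif(n) < config$missing_run_prob

    subjects <- vector("list", n)
    masks <- vector("list", n)
    for (i in seq_len(n)) {
      sub <- simulate_subject(traits[i, ], config,
                              generate_traces = generate_traces,
                              force_missing_run = force_missing[i])
      subjects[[i]] <- sub$dataset
      masks[[i]] <- sub$masks
    }
    names(subjects) <- clinical$subject
    names(masks) <- clinical$subject

    structure(list(config = config, clinical = clinical, subjects = subjects,
                   ground_truth = list(traits = traits,
                                       latent_corr = latent_corr,
                                       artifact_masks = masks,
                                       forced_missing_run = force_missing)),
              class = "cohort")
  })
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("synthetic cohort: %d subjects (%d control, %d depressed), %s\n",
              nrow(x$clinical), sum(x$clinical$group == "control"),
              sum(x$clinical$group == "depressed"),
              if (length(x$subjects[[1]]$traces)) "with traces" else "clinical only"))
  invisible(x)
}

# one subject: trial order, RTs, deadline staircase, traces, artifacts
simulate_subject <- function(trait, config, generate_traces = TRUE,
                             force_missing_run = FALSE) {
  tpc <- config$trials_per_condition
  conditions <- sample(rep(c("reward", "neutral", "control"), tpc))
  trial_index <- stats::ave(seq_along(conditions), conditions,
                            FUN = seq_along)
  n_trials <- length(conditions)
  rt <- rep(NA_real_, n_trials)
  resp <- conditions != "control"
  rt[resp] <- pmax(0.15, trait$rt_level +
                     stats::rnorm(sum(resp), 0, config$rt_sd_within))
  success <- rep(NA, n_trials)
  deadline <- rep(NA_real_, n_trials)
  is_rew <- conditions == "reward"
  st <- simulate_adaptive_deadline(rt[is_rew],
                                   initial = config$deadline_initial,
                                   step = config$deadline_step)
  success[is_rew] <- st$success
  deadline[is_rew] <- st$deadline
  success[conditions == "neutral"] <-
    rt[conditions == "neutral"] <= config$deadline_initial
  trials <- data.frame(trial = seq_len(n_trials), condition = conditions,
                       trial_index = trial_index, rt = rt, success = success,
                       deadline = deadline, stringsAsFactors = FALSE)
  traces <- list()
  masks <- list()
  if (generate_traces) {
    traces <- generate_subject_traces(trait, config, conditions = conditions)
    for (j in seq_along(traces)) {
      attr(traces[[j]], "trial") <- j
      attr(traces[[j]], "trial_index") <- trial_index[j]
      inj <- inject_artifacts(traces[[j]], config)
      traces[[j]] <- inj$trace
      masks[[j]] <- inj$mask
    }
    if (force_missing_run) {
      upd <- force_run_missingness(traces, masks, config)
      traces <- upd$traces
      masks <- upd$masks
    }
  }
  list(dataset = structure(list(subject = trait$subject, traces = traces,
                                trials = trials,
                                sampling_rate = config$sampling_rate),
                           class = "subject_dataset"),
       masks = masks)
}

#' Generate noiseless-plus-noise pupil traces for one subject
#'
#' Each trace spans the pre-cue baseline plus the anticipation window at the
#' configured sampling rate (`round(total_duration * rate) + 1` samples).
#' The noiseless pupil course is flat during baseline and linear during
#' anticipation with the subject's per-condition slope (reward and neutral
#' rise, the no-response control falls); additive AR(1) noise and fixational
#' gaze wander are superimposed.
#'
#' @param trait one row of the cohort ground-truth trait table.
#' @param config a [cohort_config()].
#' @param conditions character vector of trial conditions in presentation
#'   order; defaults to a pseudo-random interleaving of
#'   `trials_per_condition` trials per condition.
#' @return list of `pupil_trace` data.frames (columns `time`, `pupil`,
#'   `gaze_x`, `gaze_y`, `valid`) with attributes `condition`,
#'   `sampling_rate`.
#' @export
generate_subject_traces <- function(trait, config, conditions = NULL) {
  if (is.null(conditions))
    conditions <- sample(rep(c("reward", "neutral", "control"),
                             config$trials_per_condition))
  rate <- config$sampling_rate
  dt <- 1 / rate
  n_samp <- round((config$baseline_duration + config$anticipation_duration) *
                    rate) + 1L
  time <- (seq_len(n_samp) - 1L) * dt - config$baseline_duration
  ramp <- pmax(time, 0)
  K <- config$pupil_units_per_z
  phi <- config$noise_ar1
  slope <- c(reward = trait$slope_reward, neutral = trait$slope_neutral,
             control = trait$slope_control)
  n_tr <- length(conditions)
  # stationary AR(1) processes, one column per trial, filtered in one call
  ar1_matrix <- function(sd, rho_ar) {
    innov <- matrix(stats::rnorm(n_samp * n_tr, 0, sd * sqrt(1 - rho_ar^2)),
                    n_samp, n_tr)
    innov[1, ] <- stats::rnorm(n_tr, 0, sd)
    matrix(stats::filter(innov, rho_ar, "recursive"), n_samp, n_tr)
  }
  noise <- if (config$noise_sd > 0) K * ar1_matrix(config$noise_sd, phi)
           else matrix(0, n_samp, n_tr)
  gxm <- trait$fixation_x + ar1_matrix(config$gaze_wander_sd, 0.98)
  gym <- trait$fixation_y + ar1_matrix(config$gaze_wander_sd, 0.98)
  lapply(seq_len(n_tr), function(j) {
    cond <- conditions[j]
    mean_curve <- trait$baseline_level + K * slope[[cond]] * ramp
    structure(data.frame(time = time, pupil = mean_curve + noise[, j],
                         gaze_x = gxm[, j], gaze_y = gym[, j], valid = TRUE),
              class = c("pupil_trace", "data.frame"),
              condition = cond, sampling_rate = rate)
  })
}

#' Inject a single blink of known onset and duration
#'
#' Sets `round(duration * sampling_rate)` consecutive pupil samples to
#' missing, starting at `onset_index` (clipped at the trace end).
#'
#' @param trace a `pupil_trace`.
#' @param onset_index 1-based sample index of blink onset.
#' @param duration blink duration in seconds.
#' @return list with the modified `trace` and the logical `mask` of samples
#'   set to missing.
#' @export
inject_blink <- function(trace, onset_index, duration) {
  rate <- attr(trace, "sampling_rate")
  n <- nrow(trace)
  mask <- logical(n)
  len <- round(duration * rate)
  if (len >= 1) {
    idx <- onset_index:min(n, onset_index + len - 1L)
    trace$pupil[idx] <- NA_real_
    trace$valid[idx] <- FALSE
    mask[idx] <- TRUE
  }
  list(trace = trace, mask = mask)
}

#' Inject blink and gaze artifacts into a trace
#'
#' Blinks arrive as a Poisson process (`blink_rate` events per minute); each
#' blink sets `round(duration * rate)` pupil samples to missing. Gaze
#' excursions (probability `gaze_excursion_prob` per trial) displace the
#' gaze coordinates by a fixed offset for a contiguous episode. Blink
#' missingness and gaze excursions are independent processes.
#'
#' @param trace a `pupil_trace`.
#' @param config a [cohort_config()].
#' @return list with the modified `trace` and the ground-truth `mask`
#'   (logical; `TRUE` exactly at samples altered by this function).
#' @export
inject_artifacts <- function(trace, config) {
  n <- nrow(trace)
  rate <- attr(trace, "sampling_rate")
  mask <- logical(n)
  dur_s <- n / rate
  n_blinks <- stats::rpois(1, config$blink_rate / 60 * dur_s)
  if (n_blinks > 0) {
    onsets <- sample.int(n, n_blinks, replace = TRUE)
    durs <- stats::rgamma(n_blinks, shape = 4,
                          scale = config$blink_duration_mean / 4)
    for (b in seq_len(n_blinks)) {
      bl <- inject_blink(trace, onsets[b], durs[b])
      trace <- bl$trace
      mask <- mask | bl$mask
    }
  }
  if (stats::runif(1) < config$gaze_excursion_prob) {
    ex_dur <- stats::runif(1, config$gaze_excursion_duration[1],
                           config$gaze_excursion_duration[2])
    len <- max(1L, round(ex_dur * rate))
    onset <- sample.int(max(1L, n - len), 1)
    idx <- onset:min(n, onset + len - 1L)
    ang <- stats::runif(1, 0, 2 * pi)
    trace$gaze_x[idx] <- trace$gaze_x[idx] +
      config$gaze_excursion_offset * cos(ang)
    trace$gaze_y[idx] <- trace$gaze_y[idx] +
      config$gaze_excursion_offset * sin(ang)
    mask[idx] <- TRUE
  }
  list(trace = trace, mask = mask)
}

# push a run over the run-level missingness threshold with long eye closures
force_run_missingness <- function(traces, masks, config, target_frac = 0.22) {
  rate <- config$sampling_rate
  total <- sum(vapply(traces, nrow, integer(1)))
  repeat {
    missing <- sum(vapply(traces, function(tr) sum(!tr$valid), integer(1)))
    if (missing / total > target_frac) break
    j <- sample.int(length(traces), 1)
    n <- nrow(traces[[j]])
    len <- min(n, round(stats::runif(1, 2, 5) * rate))
    onset <- sample.int(max(1L, n - len), 1)
    idx <- onset:min(n, onset + len - 1L)
    traces[[j]]$pupil[idx] <- NA_real_
    traces[[j]]$valid[idx] <- FALSE
    masks[[j]][idx] <- TRUE
  }
  list(traces = traces, masks = masks)
}

#' Adaptive response-deadline staircase
#'
#' One-up/one-down staircase emulating the task's adaptive algorithm: a
#' trial succeeds when the response time is at or below the current
#' deadline; the deadline shortens by `step` after a success and lengthens
#' by `step` after a failure, so the long-run success proportion converges
#' to 50%.
#'
#' @param rt numeric vector of reward-trial response times (seconds), in
#'   presentation order (>= 1 trial).
#' @param initial starting deadline (seconds).
#' @param step staircase step (seconds).
#' @param min_deadline floor on the deadline.
#' @return list with logical `success` and the numeric `deadline` applied on
#'   each trial.
#' @export
simulate_adaptive_deadline <- function(rt, initial = 0.5, step = 0.02,
                                       min_deadline = 0.05) {
  if (length(rt) < 1) stop("simulate_adaptive_deadline: need at least one RT")
  n <- length(rt)
  success <- logical(n)
  deadline <- numeric(n)
  d <- initial
  for (i in seq_len(n)) {
    deadline[i] <- d
    success[i] <- rt[i] <= d
    d <- max(min_deadline, d + if (success[i]) -step else step)
  }
  list(success = success, deadline = deadline)
}
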