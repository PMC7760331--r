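# Pupillometry preprocessing: blink interpolation, run/trial QC, per-run
# z-scoring, first-derivative dilation, and per-subject summary measures.

#' Preprocessing parameters
#'
#' @param run_missing_threshold run excluded when the fraction of missing
#'   pupil samples over the whole run exceeds this (strictly; default 0.15).
#' @param max_gaze_outside a trial is discarded when gaze stays outside the
#'   fixation window for a contiguous episode longer than this (seconds;
#'   strictly; default 1).
#' @param max_interp_fraction a trial is discarded when more than this
#'   fraction of its samples is interpolated (strictly; default 0.5).
#' @param gaze_halfwidth,gaze_halfheight half-extent of the rectangular
#'   fixation window (pixels), centred on the subject's median gaze.
#' @param cumulative_gaze if `TRUE`, the gaze rule sums all outside samples
#'   instead of requiring one contiguous episode.
#' @param window analysis window over the anticipation period, seconds
#'   (closed; default c(0, 6)).
#' @param zscore z-transform each run (pooled over all of its samples)
#'   before scoring?
#' @return a named list of class `preprocess_params`.
#' @export
preprocess_params <- function(run_missing_threshold = 0.15,
                              max_gaze_outside = 1.0,
                              max_interp_fraction = 0.5,
                              gaze_halfwidth = 150, gaze_halfheight = 150,
                              cumulative_gaze = FALSE,
                              window = c(0, 6), zscore = TRUE) {
  stopifnot(run_missing_threshold > 0, max_gaze_outside > 0,
            max_interp_fraction > 0, length(window) == 2,
            window[1] < window[2])
  structure(as.list(environment()), class = "preprocess_params")
}

#' Linear interpolation of blink gaps
#'
#' Replaces every interior gap of invalid pupil samples with the straight
#' line between the nearest valid neighbours; leading and trailing gaps are
#' filled by extending the nearest valid value. The `interpolated` flag
#' marks exactly the originally-invalid samples. A trace with no valid
#' sample is marked unusable (attribute `usable = FALSE`) so the trial is
#' discarded downstream.
#'
#' @param trace a `pupil_trace` (columns `time`, `pupil`, `valid`).
#' @return the trace with gaps filled and an `interpolated` logical column.
#' @export
interpolate_blinks <- function(trace) {
  bad <- !trace$valid | is.na(trace$pupil)
  trace$interpolated <- bad
  if (all(bad)) {
    attr(trace, "usable") <- FALSE
    return(trace)
  }
  attr(trace, "usable") <- TRUE
  if (any(bad)) {
    filled <- stats::approx(trace$time[!bad], trace$pupil[!bad],
                            xout = trace$time, method = "linear",
                            rule = 2)$y
    trace$pupil[bad] <- filled[bad]
  }
  trace
}

#' Run-level quality control
#'
#' Computes the fraction of missing (invalid) pupil samples over the whole
#' run, before interpolation, and excludes the run when it exceeds the
#' threshold (strict inequality: exactly 15% is kept).
#'
#' @param traces list of `pupil_trace` objects for one run.
#' @param threshold exclusion threshold on the missing fraction (default
#'   0.15).
#' @return an object of class `qc_report`: list with
#'   `run_missing_fraction`, `run_excluded`, `n_samples`, `n_missing`.
#' @export
qc_run <- function(traces, threshold = 0.15) {
  if (length(traces) == 0) stop("qc_run: empty run")
  rates <- vapply(traces, function(tr) attr(tr, "sampling_rate") %||% NA_real_,
                  numeric(1))
  if (length(unique(stats::na.omit(rates))) > 1)
    stop("qc_run: traces must share a sampling rate")
  n_missing <- sum(vapply(traces, function(tr)
    sum(!tr$valid | is.na(tr$pupil)), integer(1)))
  n_total <- sum(vapply(traces, nrow, integer(1)))
  if (n_total == 0) stop("qc_run: empty run")
  frac <- n_missing / n_total
  structure(list(run_missing_fraction = frac,
                 run_excluded = frac > threshold,
                 n_samples = n_total, n_missing = n_missing,
                 threshold = threshold),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("run QC: %.2f%% missing (%d / %d samples) -> %s\n",
              100 * x$run_missing_fraction, x$n_missing, x$n_samples,
              if (x$run_excluded) "EXCLUDED" else "kept"))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Default fixation window for a run
#'
#' Rectangle centred on the subject's median gaze position over the run.
#'
#' @param traces list of `pupil_trace` objects.
#' @param halfwidth,halfheight half-extents in gaze units (pixels).
#' @return numeric `c(xmin, xmax, ymin, ymax)`.
#' @export
default_gaze_window <- function(traces, halfwidth = 150, halfheight = 150) {
  gx <- unlist(lapply(traces, `[[`, "gaze_x"))
  gy <- unlist(lapply(traces, `[[`, "gaze_y"))
  cx <- stats::median(gx, na.rm = TRUE)
  cy <- stats::median(gy, na.rm = TRUE)
  c(cx - halfwidth, cx + halfwidth, cy - halfheight, cy + halfheight)
}

#' Trial-level quality control
#'
#' Discards a trial when (i) gaze stays outside the fixation rectangle for a
#' contiguous episode longer than `max_outside` seconds (reason
#' `discarded_gaze`), or (ii) more than `max_interp` of its samples are
#' interpolated (reason `discarded_interpolation`). Both thresholds are
#' strict. A trace marked unusable by [interpolate_blinks()] is discarded
#' under the interpolation rule.
#'
#' @param trace an interpolated `pupil_trace`.
#' @param window fixation rectangle `c(xmin, xmax, ymin, ymax)`.
#' @param max_outside longest tolerated contiguous outside-window episode,
#'   seconds (default 1).
#' @param max_interp largest tolerated interpolated fraction (default 0.5).
#' @param cumulative if `TRUE`, sum all outside samples instead of requiring
#'   a contiguous episode.
#' @return list with `status` (`"kept"`, `"discarded_gaze"` or
#'   `"discarded_interpolation"`) and the measured `gaze_outside_s` and
#'   `interp_fraction`.
#' @export
qc_trial <- function(trace, window, max_outside = 1.0, max_interp = 0.5,
                     cumulative = FALSE) {
  if (length(window) != 4 || window[1] >= window[2] || window[3] >= window[4])
    stop("qc_trial: degenerate fixation window")
  rate <- attr(trace, "sampling_rate")
  outside <- trace$gaze_x < window[1] | trace$gaze_x > window[2] |
    trace$gaze_y < window[3] | trace$gaze_y > window[4]
  outside[is.na(outside)] <- FALSE
  if (cumulative) {
    out_s <- sum(outside) / rate
  } else {
    runs <- rle(outside)
    out_s <- if (any(runs$values)) max(runs$lengths[runs$values]) / rate else 0
  }
  interp_frac <- if (isFALSE(attr(trace, "usable"))) 1
                 else mean(trace$interpolated %||% rep(FALSE, nrow(trace)))
  status <- if (out_s > max_outside) "discarded_gaze"
            else if (interp_frac > max_interp) "discarded_interpolation"
            else "kept"
  list(status = status, gaze_outside_s = out_s,
       interp_fraction = interp_frac)
}

#' z-transform a run
#'
#' Pools all pupil samples of the run, subtracts the pooled mean and divides
#' by the pooled SD, applying the same affine transform uniformly to every
#' sample of every trace. Post-transform the pooled mean is 0 and the
#' pooled SD is 1.
#'
#' @param traces list of interpolated `pupil_trace` objects.
#' @return the traces in z-units (attribute `zscored = TRUE`).
#' @export
zscore_run <- function(traces) {
  all_p <- unlist(lapply(traces, `[[`, "pupil"))
  if (anyNA(all_p))
    stop("zscore_run: missing pupil values; interpolate before z-scoring")
  mu <- mean(all_p)
  sdev <- stats::sd(all_p)
  if (!is.finite(sdev) || sdev == 0)
    stop("zscore_run: zero variance over the run; cannot z-transform")
  lapply(traces, function(tr) {
    tr$pupil <- (tr$pupil - mu) / sdev
    attr(tr, "zscored") <- TRUE
    tr
  })
}

#' Pupil dilation: first derivative of pupil size
#'
#' First difference of the pupil series divided by the sampling interval.
#' The result has one element fewer than the input; element i is the slope
#' over the interval (t_i, t_{i+1}).
#'
#' @param trace a `pupil_trace` with at least two samples.
#' @return numeric vector of dilation values (z-units/s for a z-scored
#'   trace), with attribute `time` giving the interval midpoints.
#' @export
compute_dilation <- function(trace) {
  if (nrow(trace) < 2) stop("compute_dilation: need at least 2 samples")
  dt <- diff(trace$time)
  d <- diff(trace$pupil) / dt
  attr(d, "time") <- trace$time[-1] - dt / 2
  d
}

#' Window-averaged dilation (telescoping mean)
#'
#' Mean of the first-derivative dilation over all sampling intervals inside
#' the closed window; by the telescoping identity this equals
#' (endpoint - startpoint) / spanned duration, exactly.
#'
#' @param trace a `pupil_trace`.
#' @param window closed time window `c(start, end)` in seconds.
#' @return mean dilation over the window (units of pupil per second).
#' @export
window_mean_dilation <- function(trace, window = c(0, 6)) {
  eps <- 1e-9
  idx <- which(trace$time >= window[1] - eps & trace$time <= window[2] + eps)
  if (length(idx) < 2) stop("window_mean_dilation: window spans < 2 samples")
  span <- trace$time[idx[length(idx)]] - trace$time[idx[1]]
  (trace$pupil[idx[length(idx)]] - trace$pupil[idx[1]]) / span
}

#' Window-averaged pupil size
#'
#' @inheritParams window_mean_dilation
#' @return mean pupil size over the closed window.
#' @export
window_mean_size <- function(trace, window = c(0, 6)) {
  eps <- 1e-9
  idx <- which(trace$time >= window[1] - eps & trace$time <= window[2] + eps)
  if (!length(idx)) stop("window_mean_size: empty window")
  mean(trace$pupil[idx])
}

#' Per-subject derived measures
#'
#' Per-condition trial means of window-averaged pupil size and dilation,
#' the two differential dilation scores (reward minus neutral, reward minus
#' no-response control), and median response times per response condition
#' (over successful and failed trials alike). A condition with no kept
#' trial yields `NA` measures and is recorded in the `missing_conditions`
#' attribute.
#'
#' @param traces list of processed (interpolated, optionally z-scored)
#'   `pupil_trace` objects for the kept trials.
#' @param trials the subject's trial table (columns `trial`, `condition`,
#'   `rt`); used for median RTs.
#' @param kept logical vector marking which rows of `trials` were kept by
#'   QC (the traces list must align with `which(kept)`).
#' @param window analysis window, seconds.
#' @return one-row data.frame of class `derived_measures`.
#' @export
summarize_subject <- function(traces, trials, kept = NULL, window = c(0, 6)) {
  if (is.null(kept)) kept <- rep(TRUE, nrow(trials))
  if (length(traces) != sum(kept))
    stop("summarize_subject: traces must align with kept trials")
  conds <- c("reward", "neutral", "control")
  kept_cond <- trials$condition[kept]
  size <- vapply(traces, window_mean_size, numeric(1), window = window)
  dil <- vapply(traces, window_mean_dilation, numeric(1), window = window)
  mean_by <- function(v, cond) {
    sel <- kept_cond == cond
    if (!any(sel)) NA_real_ else mean(v[sel])
  }
  msize <- vapply(conds, mean_by, numeric(1), v = size)
  mdil <- vapply(conds, mean_by, numeric(1), v = dil)
  missing_conditions <- conds[!conds %in% kept_cond]
  if (length(missing_conditions))
    message("summarize_subject: no kept trials for condition(s): ",
            paste(missing_conditions, collapse = ", "))
  med_rt <- function(cond) {
    v <- trials$rt[trials$condition == cond]
    v <- v[is.finite(v)]
    if (!length(v)) NA_real_ else stats::median(v)
  }
  out <- data.frame(
    mean_size_reward = msize[["reward"]],
    mean_size_neutral = msize[["neutral"]],
    mean_size_control = msize[["control"]],
    mean_dilation_reward = mdil[["reward"]],
    mean_dilation_neutral = mdil[["neutral"]],
    mean_dilation_control = mdil[["control"]],
    diff_reward_minus_neutral = mdil[["reward"]] - mdil[["neutral"]],
    diff_reward_minus_control = mdil[["reward"]] - mdil[["control"]],
    median_rt_reward = med_rt("reward"),
    median_rt_neutral = med_rt("neutral"),
    n_kept = sum(kept))
  attr(out, "missing_conditions") <- missing_conditions
  class(out) <- c("derived_measures", "data.frame")
  out
}

#' Preprocess one subject
#'
#' Full per-subject pipeline: blink interpolation, run-level QC (on the raw
#' validity flags), per-run z-scoring, trial-level QC against the subject's
#' median-gaze fixation window, and derived-measure summarisation. Trials
#' are never reordered; the per-trial QC table preserves `trial` and
#' `trial_index`.
#'
#' @param dataset a `subject_dataset` (elements `subject`, `traces`,
#'   `trials`).
#' @param params a [preprocess_params()].
#' @return list with `derived` (one-row data.frame incl. `subject`),
#'   `run_qc` (a `qc_report`), `trial_qc` (per-trial status table),
#'   `trial_scores` (kept per-trial window-mean dilation, long format) and
#'   `traces` (processed kept traces), or, for an excluded run,
#'   `run_qc` plus `excluded = TRUE`.
#' @export
preprocess_subject <- function(dataset, params = preprocess_params()) {
  stopifnot(inherits(dataset, "subject_dataset") ||
              all(c("subject", "traces", "trials") %in% names(dataset)))
  traces <- dataset$traces
  trials <- dataset$trials
  rq <- qc_run(traces, threshold = params$run_missing_threshold)
  if (rq$run_excluded)
    return(list(subject = dataset$subject, run_qc = rq, excluded = TRUE))
  interp <- lapply(traces, interpolate_blinks)
  usable <- vapply(interp, function(tr) isTRUE(attr(tr, "usable")), logical(1))
  zs <- if (params$zscore) zscore_run(interp[usable]) else interp[usable]
  full <- interp
  full[usable] <- zs
  win <- default_gaze_window(full, params$gaze_halfwidth,
                             params$gaze_halfheight)
  tq <- lapply(full, qc_trial, window = win,
               max_outside = params$max_gaze_outside,
               max_interp = params$max_interp_fraction,
               cumulative = params$cumulative_gaze)
  status <- vapply(tq, `[[`, character(1), "status")
  status[!usable] <- "discarded_interpolation"
  trial_qc <- data.frame(
    subject = dataset$subject,
    trial = trials$trial, condition = trials$condition,
    trial_index = trials$trial_index, status = status,
    gaze_outside_s = vapply(tq, `[[`, numeric(1), "gaze_outside_s"),
    interp_fraction = vapply(tq, `[[`, numeric(1), "interp_fraction"),
    stringsAsFactors = FALSE)
  kept <- status == "kept"
  if (!any(kept))
    return(list(subject = dataset$subject, run_qc = rq, trial_qc = trial_qc,
                excluded = TRUE))
  kept_traces <- full[kept]
  derived <- summarize_subject(kept_traces, trials, kept = kept,
                               window = params$window)
  derived <- cbind(subject = dataset$subject, derived)
  scores <- data.frame(
    subject = dataset$subject,
    condition = trials$condition[kept],
    trial_index = trials$trial_index[kept],
    score = vapply(kept_traces, window_mean_dilation, numeric(1),
                   window = params$window),
    stringsAsFactors = FALSE)
  list(subject = dataset$subject, derived = derived, run_qc = rq,
       trial_qc = trial_qc, trial_scores = scores, traces = kept_traces,
       excluded = FALSE)
}

#' Preprocess a whole cohort
#'
#' Applies [preprocess_subject()] to every subject; subjects failing
#' run-level QC are excluded from all downstream analyses and listed in the
#' QC table with their exclusion reason.
#'
#' @param cohort a `cohort` from [generate_cohort()] (or [read_cohort()]).
#' @param params a [preprocess_params()].
#' @return list with `derived` (data.frame, one row per kept subject),
#'   `run_qc` (per-subject table), `trial_qc` (per-trial table over kept
#'   runs), `trial_scores` (long per-trial dilation scores) and
#'   `excluded_subjects`.
#' @export
preprocess_cohort <- function(cohort, params = preprocess_params()) {
  res <- lapply(cohort$subjects, preprocess_subject, params = params)
  excluded <- vapply(res, function(r) isTRUE(r$excluded), logical(1))
  run_qc <- do.call(rbind, lapply(res, function(r)
    data.frame(subject = r$subject,
               run_missing_fraction = r$run_qc$run_missing_fraction,
               run_excluded = r$run_qc$run_excluded,
               stringsAsFactors = FALSE)))
  rownames(run_qc) <- NULL
  kept_res <- res[!excluded]
  derived <- do.call(rbind, lapply(kept_res, `[[`, "derived"))
  trial_qc <- do.call(rbind, lapply(kept_res, `[[`, "trial_qc"))
  trial_scores <- do.call(rbind, lapply(kept_res, `[[`, "trial_scores"))
  if (!is.null(derived)) rownames(derived) <- NULL
  if (!is.null(trial_qc)) rownames(trial_qc) <- NULL
  if (!is.null(trial_scores)) rownames(trial_scores) <- NULL
  list(derived = derived, run_qc = run_qc, trial_qc = trial_qc,
       trial_scores = trial_scores,
       excluded_subjects = names(cohort$subjects)[excluded])
}
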