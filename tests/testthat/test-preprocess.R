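# Preprocessing: blink interpolation, run/trial QC, z-scoring, dilation,
# derived measures, order preservation, file round trip.

test_that("blink interpolation fills gaps linearly and extends edges", {
  # no invalid samples: unchanged
  tr <- make_trace(c(1, 2, 3, 4), rate = 1)
  out <- interpolate_blinks(tr)
  expect_equal(out$pupil, tr$pupil)
  expect_false(any(out$interpolated))
  # interior gap on a unit grid: straight line between neighbours
  tr <- make_trace(c(2, NA, NA, 5), rate = 1)
  out <- interpolate_blinks(tr)
  expect_equal(out$pupil, c(2, 3, 4, 5))
  expect_identical(out$interpolated, c(FALSE, TRUE, TRUE, FALSE))
  # leading/trailing gaps: nearest-value extension
  tr <- make_trace(c(NA, NA, 7, 9, NA), rate = 1)
  out <- interpolate_blinks(tr)
  expect_equal(out$pupil, c(7, 7, 7, 9, 9))
  # all invalid: unusable
  tr <- make_trace(c(NA_real_, NA_real_, NA_real_), rate = 1)
  expect_false(attr(interpolate_blinks(tr), "usable"))
})

test_that("interpolation error stays below the simulated noise level", {
  cfg <- cohort_config(n_control = 1, n_depressed = 1, seed = 9,
                       blink_rate = 0, gaze_excursion_prob = 0,
                       missing_run_prob = 0)
  co <- generate_cohort(cfg)
  tr <- co$subjects[[1]]$traces[[1]]
  out <- inject_blink(tr, onset_index = 400, duration = 0.1)
  filled <- interpolate_blinks(out$trace)
  rmse <- sqrt(mean((filled$pupil[out$mask] - tr$pupil[out$mask])^2))
  expect_lt(rmse, cfg$noise_sd * cfg$pupil_units_per_z)
})

test_that("run QC applies the strict 15% missingness rule", {
  mk_run <- function(frac) {
    n <- 1000
    p <- rep(5, n)
    miss <- seq_len(round(frac * n))
    p[miss] <- NA
    list(make_trace(p))
  }
  expect_true(qc_run(mk_run(0.16))$run_excluded)
  rep0 <- qc_run(mk_run(0))
  expect_false(rep0$run_excluded)
  expect_identical(rep0$run_missing_fraction, 0)
  # exactly 15.0%: kept (strict inequality)
  expect_false(qc_run(mk_run(0.15))$run_excluded)
  expect_equal(qc_run(mk_run(0.15))$run_missing_fraction, 0.15)
  expect_error(qc_run(list()), "empty run")
})

test_that("trial QC discards sustained gaze excursions and heavy interpolation", {
  win <- c(860, 1060, 440, 640)
  n <- 1500  # 6 s at 250 Hz
  # 1.2 s contiguous excursion: discarded_gaze
  gx <- rep(960, n); gx[101:400] <- 2000
  tr <- interpolate_blinks(make_trace(rnorm(n, 5), gaze_x = gx))
  expect_identical(qc_trial(tr, win)$status, "discarded_gaze")
  # 0.8 s excursion: kept under the contiguous rule
  gx <- rep(960, n); gx[101:300] <- 2000
  tr <- interpolate_blinks(make_trace(rnorm(n, 5), gaze_x = gx))
  expect_identical(qc_trial(tr, win)$status, "kept")
  # two 0.8 s excursions: discarded only in cumulative mode
  gx <- rep(960, n); gx[c(101:300, 701:900)] <- 2000
  tr <- interpolate_blinks(make_trace(rnorm(n, 5), gaze_x = gx))
  expect_identical(qc_trial(tr, win)$status, "kept")
  expect_identical(qc_trial(tr, win, cumulative = TRUE)$status,
                   "discarded_gaze")
  # 60% interpolated: discarded_interpolation
  p <- rnorm(n, 5); p[1:900] <- NA
  tr <- interpolate_blinks(make_trace(p))
  expect_identical(qc_trial(tr, win)$status, "discarded_interpolation")
  # clean centred trial: kept
  tr <- interpolate_blinks(make_trace(rnorm(n, 5)))
  expect_identical(qc_trial(tr, win)$status, "kept")
  expect_error(qc_trial(tr, c(900, 900, 400, 600)), "degenerate")
})

test_that("run z-scoring normalises pooled moments and is affine-invariant", {
  set.seed(4)
  traces <- list(make_trace(rnorm(500, 4000, 300)),
                 make_trace(rnorm(500, 4100, 250)))
  z <- zscore_run(traces)
  pool <- unlist(lapply(z, `[[`, "pupil"))
  expect_equal(mean(pool), 0, tolerance = 1e-10)
  expect_equal(sd(pool), 1, tolerance = 1e-10)
  shifted <- lapply(traces, function(tr) { tr$pupil <- 3 * tr$pupil - 7; tr })
  z2 <- zscore_run(shifted)
  expect_equal(unlist(lapply(z2, `[[`, "pupil")), pool, tolerance = 1e-10)
  expect_error(zscore_run(list(make_trace(rep(5, 10)))), "zero variance")
})

test_that("dilation is the first difference over the sampling interval", {
  expect_equal(compute_dilation(make_trace(rep(2, 100))), rep(0, 99),
               ignore_attr = TRUE)
  s <- 0.37
  tr <- make_trace(5 + s * (0:249) / 250)
  expect_equal(compute_dilation(tr), rep(s, 249), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_error(compute_dilation(make_trace(5)), "at least 2")
})

test_that("window-mean dilation telescopes exactly", {
  set.seed(10)
  tr <- make_trace(cumsum(rnorm(1751)), t0 = -1)
  d <- compute_dilation(tr)
  idx <- which(tr$time >= 0 & tr$time <= 6)
  manual <- mean(d[idx[-length(idx)]])
  expect_equal(window_mean_dilation(tr, c(0, 6)), manual, tolerance = 1e-12)
  expect_equal(window_mean_dilation(tr, c(0, 6)),
               (tr$pupil[idx[length(idx)]] - tr$pupil[idx[1]]) / 6,
               tolerance = 1e-12)
})

test_that("subject summaries combine kept trials and trial RTs", {
  trials <- data.frame(trial = 1:4,
                       condition = c("reward", "control", "reward", "neutral"),
                       trial_index = c(1, 1, 2, 1),
                       rt = c(0.5, NA, 0.3, 0.6), success = c(TRUE, NA, TRUE, FALSE))
  mk <- function(slope) make_trace(slope * (0:300) / 50, rate = 50)
  traces <- list(mk(0.4), mk(-0.2), mk(0.4), mk(0.1))
  dm <- summarize_subject(traces, trials, window = c(0, 6))
  expect_equal(dm$mean_dilation_reward, 0.4, tolerance = 1e-12)
  expect_equal(dm$diff_reward_minus_control, 0.6, tolerance = 1e-12)
  expect_equal(dm$median_rt_reward, 0.4)
  expect_equal(dm$median_rt_neutral, 0.6)
  # a single kept reward trial: its own window average
  dm2 <- summarize_subject(traces[1], trials,
                           kept = c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(dm2$mean_dilation_reward, window_mean_dilation(traces[[1]]))
  expect_true(is.na(dm2$mean_dilation_control))
  expect_identical(attr(dm2, "missing_conditions"), c("neutral", "control"))
})

test_that("noiseless subjects recover programmed slopes through preprocessing", {
  cfg <- clean_config()
  co <- generate_cohort(cfg)
  proc <- preprocess_cohort(co, preprocess_params(zscore = FALSE))
  gt <- co$ground_truth$traits
  ord <- match(proc$derived$subject, gt$subject)
  expect_equal(proc$derived$mean_dilation_reward / cfg$pupil_units_per_z,
               gt$slope_reward[ord], tolerance = 1e-12)
  expect_equal(proc$derived$diff_reward_minus_control / cfg$pupil_units_per_z,
               gt$slope_reward[ord] - gt$slope_control[ord],
               tolerance = 1e-12)
})

test_that("preprocessing preserves trial order and indices", {
  co <- generate_cohort(tiny_config())
  proc <- suppressMessages(preprocess_cohort(co))
  for (s in unique(proc$trial_qc$subject)) {
    tq <- proc$trial_qc[proc$trial_qc$subject == s, ]
    expect_identical(tq$trial, sort(tq$trial))
    orig <- co$subjects[[s]]$trials
    expect_identical(tq$condition, orig$condition)
    expect_identical(tq$trial_index, orig$trial_index)
  }
  # kept per-trial scores carry their provenance
  expect_true(all(proc$trial_scores$trial_index >= 1))
})

test_that("raising the blink rate never lowers expected trial discards", {
  rates <- c(5, 120)
  mean_discarded <- vapply(rates, function(br) {
    cfg <- cohort_config(n_control = 1, n_depressed = 1, sampling_rate = 50,
                         trials_per_condition = 2, blink_rate = br,
                         blink_duration_mean = 0.3, gaze_excursion_prob = 0,
                         missing_run_prob = 0, seed = 1)
    set.seed(37)
    mean(vapply(1:100, function(i) {
      trait <- data.frame(subject = "s", slope_reward = 0.25,
                          slope_neutral = 0.12, slope_control = -0.15,
                          baseline_level = 4000, fixation_x = 960,
                          fixation_y = 540)
      traces <- generate_subject_traces(trait, cfg)
      sum(vapply(traces, function(tr) {
        out <- inject_artifacts(tr, cfg)
        qc_trial(interpolate_blinks(out$trace),
                 c(760, 1160, 340, 740))$status != "kept"
      }, logical(1)))
    }, numeric(1)))
  }, numeric(1))
  expect_gte(mean_discarded[2], mean_discarded[1])
})

test_that("a processed run survives a file round trip to 1e-9", {
  co <- generate_cohort(tiny_config())
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  co2 <- read_cohort(dir)
  expect_identical(names(co2$subjects), names(co$subjects))
  for (s in names(co$subjects)) {
    for (j in seq_along(co$subjects[[s]]$traces)) {
      a <- co$subjects[[s]]$traces[[j]]
      b <- co2$subjects[[s]]$traces[[j]]
      expect_identical(is.na(a$pupil), is.na(b$pupil))
      expect_lt(max(abs(a$pupil - b$pupil), na.rm = TRUE), 1e-9)
      expect_identical(a$valid, b$valid)
      expect_identical(attr(a, "condition"), attr(b, "condition"))
    }
  }
  # derived measures agree after the round trip
  p1 <- suppressMessages(preprocess_cohort(co))
  p2 <- suppressMessages(preprocess_cohort(co2))
  expect_equal(p1$derived$mean_dilation_reward,
               p2$derived$mean_dilation_reward, tolerance = 1e-9)
})
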