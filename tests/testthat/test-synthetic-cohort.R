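# Synthetic cohort generator: determinism, calibration, trace geometry,
# artifact bookkeeping, adaptive deadline.

test_that("identical config and seed give byte-identical cohorts", {
  cfg <- tiny_config()
  expect_identical(generate_cohort(cfg), generate_cohort(cfg))
  cfg2 <- tiny_config()
  cfg2$seed <- 43L
  expect_false(identical(generate_cohort(cfg), generate_cohort(cfg2)))
})

test_that("cohort generation does not disturb the global RNG stream", {
  set.seed(123)
  a <- runif(1)
  set.seed(123)
  invisible(generate_cohort(tiny_config(), generate_traces = FALSE))
  expect_identical(runif(1), a)
})

test_that("clinical scores respect group structure", {
  co <- generate_cohort(cohort_config(n_control = 40, n_depressed = 60,
                                      seed = 3, missing_run_prob = 0),
                        generate_traces = FALSE)
  cl <- co$clinical
  expect_true(all(cl$symptom_count[cl$group == "control"] <= 3))
  expect_true(all(cl$symptom_count >= 0 & cl$symptom_count <= 9))
  expect_identical(cl$acute_flag, cl$symptom_count >= 5)
  expect_true(all(cl$symptom_impact >= 0 & cl$symptom_impact <= 10))
  expect_true(all(cl$anhedonia >= 0))
})

test_that("copula calibration realises the target correlation at large n", {
  for (tgt in c(0, -0.5)) {
    cfg <- cohort_config(n_control = 760, n_depressed = 1240,
                         target_corr_dilation_symptoms = tgt, seed = 11,
                         missing_run_prob = 0)
    co <- generate_cohort(cfg, generate_traces = FALSE)
    realized <- cor(co$ground_truth$traits$slope_reward,
                    co$clinical$symptom_count)
    expect_lt(abs(realized - tgt), 0.05)
  }
})

test_that("population dilation slopes are condition-ordered", {
  co <- generate_cohort(cohort_config(n_control = 100, n_depressed = 100,
                                      seed = 5, missing_run_prob = 0),
                        generate_traces = FALSE)
  gt <- co$ground_truth$traits
  expect_gt(mean(gt$slope_reward), mean(gt$slope_neutral))
  expect_gt(mean(gt$slope_neutral), 0)
  expect_lt(mean(gt$slope_control), 0)
})

test_that("an infeasible target correlation raises a configuration error", {
  cfg <- tiny_config()
  cfg$target_corr_dilation_symptoms <- -0.99
  expect_error(generate_cohort(cfg, generate_traces = FALSE), "infeasible")
})

test_that("traces have the configured geometry", {
  co <- generate_cohort(clean_config())
  tr <- co$subjects[[1]]$traces[[1]]
  # round(total duration x rate) + 1 samples; 1501 anticipation samples
  expect_identical(nrow(tr), as.integer(round(7 * 250) + 1))
  expect_identical(sum(tr$time >= -1e-12), 1501L)
  expect_equal(diff(tr$time), rep(1 / 250, nrow(tr) - 1), tolerance = 1e-12)
})

test_that("noiseless traces carry the programmed slopes exactly", {
  cfg <- clean_config()
  co <- generate_cohort(cfg)
  gt <- co$ground_truth$traits
  for (i in seq_along(co$subjects)) {
    sub <- co$subjects[[i]]
    for (tr in sub$traces) {
      cond <- attr(tr, "condition")
      slope <- gt[[paste0("slope_", cond)]][i]
      measured <- window_mean_dilation(tr, c(0, 6)) / cfg$pupil_units_per_z
      expect_equal(measured, slope, tolerance = 1e-12)
    }
  }
  # pupil constriction for the no-response control stimulus
  expect_true(all(gt$slope_control < 0))
})

test_that("artifact injection is the identity at zero rates", {
  cfg <- clean_config()
  co <- generate_cohort(cfg)
  tr <- co$subjects[[1]]$traces[[1]]
  out <- inject_artifacts(tr, cfg)
  expect_identical(out$trace, tr)
  expect_false(any(out$mask))
})

test_that("a 200 ms blink at 250 Hz flags exactly 50 samples", {
  tr <- make_trace(rep(5, 1000), rate = 250)
  out <- inject_blink(tr, onset_index = 101, duration = 0.2)
  expect_identical(sum(out$mask), 50L)
  expect_identical(sum(is.na(out$trace$pupil)), 50L)
  expect_identical(which(out$mask), 101:150)
})

test_that("blink counts follow the configured Poisson rate", {
  cfg <- cohort_config(n_control = 1, n_depressed = 1, blink_rate = 5,
                       blink_duration_mean = 0.15, gaze_excursion_prob = 0,
                       missing_run_prob = 0, seed = 1)
  tr <- make_trace(rep(5, 1750), rate = 250)  # 7 s
  set.seed(91)
  n_rep <- 300
  episodes <- sum(vapply(seq_len(n_rep), function(i) {
    out <- inject_artifacts(tr, cfg)
    runs <- rle(!out$trace$valid)
    sum(runs$values)
  }, numeric(1)))
  lambda <- n_rep * 7 / 60 * cfg$blink_rate  # expected blink count
  expect_lt(abs(episodes - lambda), 3 * sqrt(lambda))
})

test_that("the artifact mask equals the set of altered samples", {
  cfg <- cohort_config(n_control = 1, n_depressed = 1, blink_rate = 30,
                       gaze_excursion_prob = 1, missing_run_prob = 0,
                       seed = 2)
  co_clean <- generate_cohort(clean_config(n_control = 1, n_depressed = 1))
  tr <- co_clean$subjects[[1]]$traces[[1]]
  set.seed(17)
  out <- inject_artifacts(tr, cfg)
  altered <- (is.na(out$trace$pupil) & !is.na(tr$pupil)) |
    out$trace$gaze_x != tr$gaze_x | out$trace$gaze_y != tr$gaze_y |
    out$trace$valid != tr$valid
  expect_identical(out$mask, altered)
  expect_gt(sum(out$mask), 0)
})

test_that("the adaptive deadline staircase converges to 50% success", {
  # deadline far above all RTs: first trial succeeds
  st <- simulate_adaptive_deadline(rep(0.4, 5), initial = 10)
  expect_true(st$success[1])
  # constant RT, 200 trials: success fraction in [0.4, 0.6]
  st <- simulate_adaptive_deadline(rep(0.45, 200))
  expect_gte(mean(st$success), 0.4)
  expect_lte(mean(st$success), 0.6)
  # stationary RT distribution, 10,000 trials: within 0.02 of 0.5
  set.seed(21)
  rts <- pmax(0.15, rnorm(10000, 0.45, 0.08))
  st <- simulate_adaptive_deadline(rts)
  expect_lt(abs(mean(st$success) - 0.5), 0.02)
  expect_error(simulate_adaptive_deadline(numeric(0)), "at least one")
})

test_that("config validation rejects out-of-range parameters", {
  expect_error(cohort_config(n_control = 0), "count")
  expect_error(cohort_config(target_corr_dilation_symptoms = -1), "inside")
  expect_error(cohort_config(gaze_excursion_prob = 1.5), "probability")
  expect_error(cohort_config(anticipation_duration = 0), "> 0")
  expect_error(cohort_config(noise_ar1 = 1), "inside")
})
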