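# Measurement-error latent-correlation model: priors, sampler determinism,
# recovery, directional BF, attenuation diagnostics.

fit_quick <- function(model, seed = 1, draws = 2500, warmup = 1000) {
  run_mcmc(model, chains = 2L, draws = draws, warmup = warmup, seed = seed)
}

test_that("model construction validates inputs and priors", {
  set.seed(22)
  d <- simulate_latent_pairs(41, -0.5, c(0.94, 0.78))
  m <- measurement_model(d$x, d$y, attr(d, "sem_x"), attr(d, "sem_y"))
  expect_s3_class(m, "measurement_model")
  expect_identical(m$n, 41L)
  expect_error(measurement_model(1:5, 1:4, 0, 0), "equal length")
  expect_error(measurement_model(1:3, 1:3, 0, 0), "n >= 4")
  expect_error(measurement_model(d$x, d$y, -0.1, 0), ">= 0")
  expect_error(measurement_priors(rho = c(-2, 1)), "within")
  expect_error(measurement_priors(mean_x = c(2, -2)), "lower < upper")
  expect_warning(measurement_model(d$x + 100, d$y, 0.1, 0.1), "prior support")
})

test_that("identical seeds give identical posterior draws", {
  set.seed(23)
  d <- simulate_latent_pairs(41, -0.5, c(0.94, 0.78))
  m <- measurement_model(d$x, d$y, attr(d, "sem_x"), attr(d, "sem_y"))
  s1 <- fit_quick(m, seed = 5)
  s2 <- fit_quick(m, seed = 5)
  expect_identical(s1$rho, s2$rho)
  s3 <- fit_quick(m, seed = 6)
  expect_false(identical(s1$rho, s3$rho))
})

test_that("zero-measurement-error fits match the sufficient-statistic posterior", {
  # with sem = 0 the model is a plain bivariate-normal fit; its rho
  # posterior agrees with the uniform-prior posterior built from the exact
  # sampling density of r (independent route)
  set.seed(24)
  n <- 200
  d <- simulate_latent_pairs(n, -0.4, c(1, 1))
  m <- measurement_model(d$x, d$y, 0, 0)
  s <- fit_quick(m, seed = 2)
  r_obs <- pearson_r(d$x, d$y)
  post_mean_ref <- integrate(function(rho)
    rho * sapply(rho, r_sampling_density, r = r_obs, n = n), -1, 1)$value /
    integrate(function(rho)
      sapply(rho, r_sampling_density, r = r_obs, n = n), -1, 1)$value
  expect_lt(abs(mean(s$rho) - post_mean_ref), 0.05)
})

test_that("null latent correlation is recovered at large n", {
  set.seed(25)
  d <- simulate_latent_pairs(2000, 0, c(1, 1))
  m <- measurement_model(d$x, d$y, 0, 0)
  s <- fit_quick(m, seed = 3)
  expect_lt(abs(mean(s$rho)), 0.05)
  expect_true(attr(s, "converged"))
})

test_that("sampling with no data reproduces the priors", {
  m <- measurement_model(c(0, 0.1, -0.1, 0.2), c(5, 6, 4, 5), 0.2, 1)
  s <- run_mcmc(m, chains = 2L, draws = 5000L, warmup = 500L, seed = 4,
                sample_prior = TRUE)
  ks <- function(x, lo, hi)
    suppressWarnings(ks.test(x, "punif", lo, hi)$statistic)
  expect_lt(ks(s$rho, -1, 1), 0.05)
  expect_lt(ks(s$mean_x, -2, 2), 0.05)
  expect_lt(ks(s$mean_y, 0, 20), 0.05)
  expect_lt(ks(s$sd_x, 0, 2), 0.05)
  expect_lt(ks(s$sd_y, 0, 10), 0.05)
})

test_that("directional BF uses analytic prior odds and flags one-sided mass", {
  m <- measurement_model(c(0, 0.1, -0.1, 0.2), c(5, 6, 4, 5), 0.2, 1)
  s_prior <- run_mcmc(m, chains = 2L, draws = 5000L, warmup = 500L, seed = 9,
                      sample_prior = TRUE)
  # posterior identical to prior: BF ~ 1
  db <- directional_bf(s_prior, -0.3)
  expect_equal(db$prior_prob, 0.35)
  expect_lt(abs(log10(db$bf)), 0.1)
  # strong negative truth: BF(rho < -0.3) well above 10
  set.seed(26)
  d <- simulate_latent_pairs(200, -0.6, c(0.95, 0.95))
  m2 <- measurement_model(d$x, d$y, attr(d, "sem_x"), attr(d, "sem_y"))
  s2 <- fit_quick(m2, seed = 7)
  db2 <- suppressWarnings(directional_bf(s2, -0.3))
  expect_gt(db2$bf, 10)
  # threshold outside the prior support is rejected
  expect_error(directional_bf(s2, -1.5), "inside the rho prior")
  # degenerate mass is flagged as a bound
  expect_warning(db3 <- directional_bf(s2, 0.999), "bound")
  expect_true(db3$bounded)
})

test_that("attenuation diagnostic orders naive, disattenuated and model estimates", {
  set.seed(27)
  # perfect reliability: all three estimates agree
  d <- simulate_latent_pairs(400, -0.5, c(1, 1))
  m <- measurement_model(d$x, d$y, 0, 0)
  s <- fit_quick(m, seed = 8)
  ad <- attenuation_diagnostic(s, d$x, d$y, c(1, 1))
  expect_lt(max(abs(ad$value - ad$value[1])), 0.05)
  # imperfect reliability: model estimate exceeds naive r in magnitude
  for (seed in 1:3) {
    set.seed(100 + seed)
    d <- simulate_latent_pairs(300, -0.5, c(0.8, 0.8))
    m <- measurement_model(d$x, d$y, attr(d, "sem_x"), attr(d, "sem_y"))
    s <- fit_quick(m, seed = seed)
    ad <- attenuation_diagnostic(s, d$x, d$y, c(0.8, 0.8))
    naive <- ad$value[ad$estimate == "naive_pearson"]
    model <- ad$value[ad$estimate == "model_posterior_mean"]
    expect_gte(abs(model) + 0.03, abs(naive))
  }
})

test_that("upper and lower pupil reliabilities give compatible conclusions", {
  set.seed(28)
  d <- simulate_latent_pairs(41, -0.55, c(0.94, 0.78))
  fits <- lapply(c(0.94, 0.7), function(rel_x) {
    m <- measurement_model(d$x, d$y,
                           sem_from_reliability(sd(d$x), rel_x),
                           sem_from_reliability(sd(d$y), 0.78))
    summary(fit_quick(m, seed = 11))
  })
  rho <- lapply(fits, function(s) s[s$parameter == "rho", ])
  gap <- abs(rho[[1]]$mean - rho[[2]]$mean)
  expect_lt(gap, 0.2)                     # reported, bounded difference
  expect_identical(sign(rho[[1]]$mean), sign(rho[[2]]$mean))
  # overlapping 95% credible intervals
  expect_lt(max(rho[[1]]$q2.5, rho[[2]]$q2.5),
            min(rho[[1]]$q97.5, rho[[2]]$q97.5))
})

test_that("posterior summaries expose convergence diagnostics", {
  set.seed(29)
  d <- simulate_latent_pairs(60, -0.4, c(0.9, 0.8))
  m <- measurement_model(d$x, d$y, attr(d, "sem_x"), attr(d, "sem_y"))
  s <- fit_quick(m, seed = 12)
  sm <- summary(s)
  expect_setequal(sm$parameter, c("mean_x", "mean_y", "sd_x", "sd_y", "rho"))
  expect_true(all(is.finite(sm$rhat)))
  expect_true(all(sm$ess > 100))
  expect_true(all(s$rho > -1 & s$rho < 1))
  expect_true(all(s$sd_x >= 0 & s$sd_x <= 2))
})
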