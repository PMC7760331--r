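# End-to-end orchestration: simulate -> preprocess -> score -> reliability
# -> Bayes-factor inference -> measurement-error latent correlation.

#' Analysis plan
#'
#' Declares which variable pairs are correlated in which samples, which
#' group contrasts are tested, and which pair is fed into the
#' measurement-error latent-correlation model.
#'
#' @param correlation_pairs data.frame with columns `x`, `y`, `sample`
#'   (`"all"` or `"depressed"`) and `covariates` (comma-separated names or
#'   `""`).
#' @param group_measures derived measures compared between groups.
#' @param groupings `"group"` (all depressed vs controls) and/or `"acute"`
#'   (the symptom-count >= 5 subgroup vs controls).
#' @param cauchy_scale JZS prior scale for the group contrasts.
#' @param latent_pair length-2 character: the (x, y) pair for the
#'   measurement-error model (depressed sample).
#' @param reliability_x candidate test-retest reliabilities for the pupil
#'   measure; the model is run once per value and the results compared.
#' @param reliability_y reliability of the symptom score.
#' @param directional_threshold threshold for the directional interval BF on
#'   the latent correlation.
#' @return an object of class `analysis_plan`.
#' @export
analysis_plan <- function(
    correlation_pairs = default_correlation_pairs(),
    group_measures = c("mean_dilation_reward", "mean_dilation_neutral",
                       "mean_dilation_control", "diff_reward_minus_neutral",
                       "diff_reward_minus_control"),
    groupings = c("group", "acute"),
    cauchy_scale = 0.7,
    latent_pair = c("mean_dilation_reward", "symptom_count"),
    reliability_x = c(0.94, 0.7),
    reliability_y = 0.78,
    directional_threshold = -0.3) {
  stopifnot(all(c("x", "y", "sample", "covariates") %in%
                  names(correlation_pairs)))
  structure(as.list(environment()), class = "analysis_plan")
}

#' @rdname analysis_plan
#' @export
default_correlation_pairs <- function() {
  clin <- c("symptom_count", "symptom_impact", "anhedonia")
  rbind(
    expand.grid(x = "mean_dilation_reward", y = clin,
                sample = c("all", "depressed"), covariates = "",
                stringsAsFactors = FALSE),
    expand.grid(x = "mean_dilation_reward", y = clin, sample = "all",
                covariates = "age,sex", stringsAsFactors = FALSE),
    data.frame(x = c("mean_dilation_reward", "mean_dilation_neutral"),
               y = c("median_rt_reward", "median_rt_neutral"),
               sample = "all", covariates = "", stringsAsFactors = FALSE))
}

join_tables <- function(derived, clinical) {
  stopifnot("subject" %in% names(derived), "subject" %in% names(clinical))
  merge(derived, clinical, by = "subject", sort = TRUE)
}

select_sample <- function(tab, sample) {
  switch(sample,
         all = tab,
         depressed = tab[tab$group == "depressed", , drop = FALSE],
         acute = tab[tab$group == "depressed" & tab$acute_flag, ,
                     drop = FALSE],
         stop("unknown sample: ", sample))
}

#' Correlate derived pupil measures with clinical scores
#'
#' Runs the planned Bayesian correlation tests: for each (x, y, sample) row
#' of the plan, listwise-deletes missing values, computes the Pearson
#' correlation and its default Bayes factor (two-sided stretched beta prior,
#' width 1), or the covariate-adjusted variant via
#' [partial_correlation_bf()]. Every row carries the n actually used after
#' QC joins and deletion.
#'
#' @param derived per-subject derived-measures table.
#' @param clinical clinical table.
#' @param plan an [analysis_plan()].
#' @return data.frame: one row per test with `x`, `y`, `sample`,
#'   `covariates`, `n`, `r`, `bf10`, `log10_bf10`, `band`.
#' @export
correlate_with_symptoms <- function(derived, clinical,
                                    plan = analysis_plan()) {
  tab <- join_tables(derived, clinical)
  if (!nrow(tab)) stop("correlate_with_symptoms: empty joined table")
  pairs <- plan$correlation_pairs
  out <- lapply(seq_len(nrow(pairs)), function(i) {
    p <- pairs[i, ]
    for (v in c(p$x, p$y))
      if (!v %in% names(tab))
        stop("correlate_with_symptoms: variable not found: ", v)
    d <- select_sample(tab, p$sample)
    covs <- if (nzchar(p$covariates))
      strsplit(p$covariates, ",")[[1]] else character(0)
    use <- stats::complete.cases(d[, c(p$x, p$y, covs), drop = FALSE])
    d <- d[use, , drop = FALSE]
    res <- if (length(covs))
      partial_correlation_bf(d[[p$x]], d[[p$y]], d[covs])
    else correlation_bf(nrow(d), pearson_r(d[[p$x]], d[[p$y]]))
    data.frame(x = p$x, y = p$y, sample = p$sample,
               covariates = p$covariates, n = nrow(d),
               r = res$statistic, bf10 = res$bf10,
               log10_bf10 = res$log10_bf10, band = res$band,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Group comparisons of derived measures
#'
#' JZS Bayesian two-sample t tests per measure, for the full depressed group
#' versus controls and for the acute subgroup (symptom count >= 5) versus
#' controls.
#'
#' @param derived per-subject derived-measures table.
#' @param clinical clinical table.
#' @param measures derived measures to compare.
#' @param groupings `"group"`, `"acute"` or both.
#' @param cauchy_scale JZS Cauchy prior scale (default 0.7).
#' @return data.frame: one row per (grouping, measure) with group sizes, t,
#'   `bf10` and evidence band.
#' @export
compare_groups <- function(derived, clinical,
                           measures = c("mean_dilation_reward",
                                        "mean_dilation_neutral",
                                        "mean_dilation_control",
                                        "diff_reward_minus_neutral",
                                        "diff_reward_minus_control"),
                           groupings = c("group", "acute"),
                           cauchy_scale = 0.7) {
  tab <- join_tables(derived, clinical)
  out <- list()
  for (g in groupings) {
    test_grp <- select_sample(tab, if (g == "group") "depressed" else "acute")
    ctrl <- tab[tab$group == "control", , drop = FALSE]
    if (!nrow(test_grp) || !nrow(ctrl))
      stop("compare_groups: empty group after QC for grouping '", g, "'")
    for (m in measures) {
      if (!m %in% names(tab)) stop("compare_groups: measure not found: ", m)
      a <- test_grp[[m]][is.finite(test_grp[[m]])]
      b <- ctrl[[m]][is.finite(ctrl[[m]])]
      res <- jzs_ttest_bf(x = a, y = b, cauchy_scale = cauchy_scale)
      out[[length(out) + 1L]] <- data.frame(
        grouping = g, measure = m, n_test = length(a), n_control = length(b),
        t = res$statistic, bf10 = res$bf10, log10_bf10 = res$log10_bf10,
        band = res$band, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Run the full pipeline
#'
#' Simulate (or load) a cohort, preprocess it, estimate split-half
#' reliability, run the planned correlation and group-contrast Bayes-factor
#' analyses, and (optionally) fit the measurement-error latent-correlation
#' model for the planned pair in the depressed sample, once per candidate
#' pupil reliability. Deterministic given the config seed; excluded runs
#' and dropped subjects are recorded in the QC tables.
#'
#' @param config a [cohort_config()], or a path to a YAML config file, or a
#'   directory containing a previously written cohort.
#' @param plan an [analysis_plan()].
#' @param params a [preprocess_params()].
#' @param out_dir if non-`NULL`, all stage outputs are written there as
#'   delimited text.
#' @param latent fit the latent-correlation model? (the slowest stage).
#' @param mcmc list of MCMC settings (`chains`, `draws`, `warmup`).
#' @return an object of class `report_bundle`: list with `qc`, `derived`,
#'   `reliability`, `correlations`, `group_contrasts`, `latent`,
#'   `provenance`.
#' @export
run_pipeline <- function(config, plan = analysis_plan(),
                         params = preprocess_params(), out_dir = NULL,
                         latent = TRUE,
                         mcmc = list(chains = 3L, draws = 2000L,
                                     warmup = 1000L)) {
  cohort <- if (inherits(config, "cohort_config")) generate_cohort(config)
  else if (dir.exists(config)) read_cohort(config)
  else generate_cohort(read_cohort_config(config))
  config <- cohort$config
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_cohort(cohort, file.path(out_dir, "cohort"))
  }

  proc <- preprocess_cohort(cohort, params)
  if (is.null(proc$derived) || !nrow(proc$derived))
    stop("run_pipeline: preprocessing left no usable subjects")

  reliability <- reliability_by_condition(
    proc$trial_scores, trials_per_condition = config$trials_per_condition)

  correlations <- correlate_with_symptoms(proc$derived, cohort$clinical, plan)
  group_contrasts <- compare_groups(proc$derived, cohort$clinical,
                                    measures = plan$group_measures,
                                    groupings = plan$groupings,
                                    cauchy_scale = plan$cauchy_scale)

  latent_res <- NULL
  if (latent) {
    tab <- select_sample(join_tables(proc$derived, cohort$clinical),
                         "depressed")
    x <- tab[[plan$latent_pair[1]]]
    y <- tab[[plan$latent_pair[2]]]
    ok <- is.finite(x) & is.finite(y)
    x <- x[ok]; y <- y[ok]
    latent_res <- lapply(plan$reliability_x, function(rel_x) {
      mod <- measurement_model(
        x, y,
        sem_x = sem_from_reliability(stats::sd(x), rel_x),
        sem_y = sem_from_reliability(stats::sd(y), plan$reliability_y))
      draws <- run_mcmc(mod, chains = mcmc$chains, draws = mcmc$draws,
                        warmup = mcmc$warmup, seed = config$seed)
      list(reliability_x = rel_x, summary = summary(draws),
           directional = directional_bf(draws, plan$directional_threshold),
           attenuation = attenuation_diagnostic(
             draws, x, y, c(rel_x, plan$reliability_y)),
           draws = draws)
    })
    names(latent_res) <- paste0("rel_x_", plan$reliability_x)
  }

  cfg_file <- tempfile(fileext = ".yaml")
  write_cohort_config(config, cfg_file)
  provenance <- list(config_md5 = unname(tools::md5sum(cfg_file)),
                     seed = config$seed,
                     n_after_qc = nrow(proc$derived),
                     excluded_subjects = proc$excluded_subjects,
                     package_version =
                       as.character(utils::packageVersion("pupilarousal")))
  unlink(cfg_file)

  bundle <- structure(list(qc = proc[c("run_qc", "trial_qc",
                                       "excluded_subjects")],
                           derived = proc$derived,
                           trial_scores = proc$trial_scores,
                           reliability = reliability,
                           correlations = correlations,
                           group_contrasts = group_contrasts,
                           latent = latent_res,
                           provenance = provenance),
                      class = "report_bundle")
  if (!is.null(out_dir)) write_report_bundle(bundle, out_dir)
  bundle
}

#' @export
print.report_bundle <- function(x, ...) {
  cat("reward-anticipation pupillometry report\n")
  cat(sprintf("  subjects after QC: %d (excluded: %d)\n",
              x$provenance$n_after_qc,
              length(x$provenance$excluded_subjects)))
  cat("  correlations:\n")
  print(x$correlations, digits = 3)
  cat("  group contrasts:\n")
  print(x$group_contrasts, digits = 3)
  if (!is.null(x$latent)) {
    for (nm in names(x$latent)) {
      l <- x$latent[[nm]]
      rho <- l$summary[l$summary$parameter == "rho", ]
      cat(sprintf(
        "  latent correlation (pupil reliability %.2f): %.3f [%.3f, %.3f], BF(rho < %.2g) = %.3g\n",
        l$reliability_x, rho$mean, rho$q2.5, rho$q97.5,
        l$directional$threshold, l$directional$bf))
    }
  }
  invisible(x)
}

#' Write all report tables as delimited text
#'
#' @param bundle a `report_bundle`.
#' @param out_dir output directory.
#' @return invisibly, `out_dir`.
#' @export
write_report_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(obj, name) if (!is.null(obj))
    data.table::fwrite(obj, file.path(out_dir, name), sep = "\t")
  w(bundle$qc$run_qc, "qc_runs.tsv")
  w(bundle$qc$trial_qc, "qc_trials.tsv")
  w(bundle$derived, "derived_measures.tsv")
  w(bundle$reliability, "reliability.tsv")
  w(bundle$correlations, "correlations.tsv")
  w(bundle$group_contrasts, "group_contrasts.tsv")
  if (!is.null(bundle$latent))
    for (nm in names(bundle$latent))
      write_draws(bundle$latent[[nm]]$draws, out_dir,
                  prefix = paste0("latent_", nm))
  yaml::write_yaml(bundle$provenance, file.path(out_dir, "provenance.yaml"))
  invisible(out_dir)
}
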