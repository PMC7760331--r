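# Delimited-text persistence of cohorts: one trace file per subject-run, a
# clinical table, a trial table, a manifest, and the YAML config.

#' Write a cohort to a directory of delimited text files
#'
#' Layout: `config.yaml`, `clinical.tsv` (one row per subject),
#' `trials.tsv` (one row per trial with condition, RT, success, deadline and
#' sample count), `manifest.tsv` (subject -> trace file), and
#' `traces/<subject>.tsv` with columns `time_s`, `pupil`, `gaze_x`,
#' `gaze_y`, `valid`; trials are concatenated in presentation order and
#' recovered from the per-trial sample counts. Ground-truth traits (a
#' synthetic-data artifact, not an observable) go to
#' `ground_truth_synthetic.tsv` when requested.
#'
#' @param cohort a `cohort`.
#' @param dir output directory (created if needed).
#' @param ground_truth also write the synthetic ground-truth trait table?
#' @return invisibly, `dir`.
#' @export
write_cohort <- function(cohort, dir, ground_truth = TRUE) {
  stopifnot(inherits(cohort, "cohort"))
  dir.create(file.path(dir, "traces"), recursive = TRUE, showWarnings = FALSE)
  write_cohort_config(cohort$config, file.path(dir, "config.yaml"))
  data.table::fwrite(cohort$clinical, file.path(dir, "clinical.tsv"),
                     sep = "\t")
  trials <- do.call(rbind, lapply(cohort$subjects, function(s) {
    tr <- s$trials
    tr$subject <- s$subject
    tr$n_samples <- if (length(s$traces))
      vapply(s$traces, nrow, integer(1)) else NA_integer_
    tr
  }))
  rownames(trials) <- NULL
  data.table::fwrite(trials, file.path(dir, "trials.tsv"), sep = "\t")
  manifest <- data.frame(
    subject = vapply(cohort$subjects, `[[`, character(1), "subject"),
    trace_file = NA_character_, stringsAsFactors = FALSE)
  for (i in seq_along(cohort$subjects)) {
    s <- cohort$subjects[[i]]
    if (!length(s$traces)) next
    fn <- file.path("traces", paste0(s$subject, ".tsv"))
    manifest$trace_file[i] <- fn
    tab <- do.call(rbind, lapply(s$traces, function(tr)
      data.frame(time_s = tr$time, pupil = tr$pupil, gaze_x = tr$gaze_x,
                 gaze_y = tr$gaze_y, valid = tr$valid)))
    data.table::fwrite(tab, file.path(dir, fn), sep = "\t")
  }
  data.table::fwrite(manifest, file.path(dir, "manifest.tsv"), sep = "\t")
  if (ground_truth && !is.null(cohort$ground_truth))
    data.table::fwrite(cohort$ground_truth$traits,
                       file.path(dir, "ground_truth_synthetic.tsv"),
                       sep = "\t")
  invisible(dir)
}

#' Read a cohort from a directory written by [write_cohort()]
#'
#' @param dir cohort directory.
#' @return a `cohort` (ground truth included when the synthetic trait table
#'   is present; artifact masks are not persisted).
#' @export
read_cohort <- function(dir) {
  config <- read_cohort_config(file.path(dir, "config.yaml"))
  clinical <- as.data.frame(data.table::fread(file.path(dir, "clinical.tsv")))
  trials_all <- as.data.frame(data.table::fread(file.path(dir, "trials.tsv")))
  manifest <- as.data.frame(data.table::fread(file.path(dir, "manifest.tsv")))
  subjects <- vector("list", nrow(manifest))
  for (i in seq_len(nrow(manifest))) {
    subj <- manifest$subject[i]
    trials <- trials_all[trials_all$subject == subj,
                         setdiff(names(trials_all), "subject")]
    rownames(trials) <- NULL
    traces <- list()
    if (!is.na(manifest$trace_file[i])) {
      tab <- as.data.frame(data.table::fread(file.path(dir,
                                                       manifest$trace_file[i])))
      starts <- cumsum(c(1L, trials$n_samples))
      traces <- lapply(seq_len(nrow(trials)), function(j) {
        rows <- starts[j]:(starts[j + 1L] - 1L)
        structure(data.frame(time = tab$time_s[rows], pupil = tab$pupil[rows],
                             gaze_x = tab$gaze_x[rows],
                             gaze_y = tab$gaze_y[rows],
                             valid = as.logical(tab$valid[rows])),
                  class = c("pupil_trace", "data.frame"),
                  condition = trials$condition[j],
                  trial = trials$trial[j],
                  trial_index = trials$trial_index[j],
                  sampling_rate = config$sampling_rate)
      })
    }
    trials$n_samples <- NULL
    subjects[[i]] <- structure(list(subject = subj, traces = traces,
                                    trials = trials,
                                    sampling_rate = config$sampling_rate),
                               class = "subject_dataset")
  }
  names(subjects) <- manifest$subject
  gt_path <- file.path(dir, "ground_truth_synthetic.tsv")
  ground_truth <- if (file.exists(gt_path))
    list(traits = as.data.frame(data.table::fread(gt_path))) else NULL
  structure(list(config = config, clinical = clinical, subjects = subjects,
                 ground_truth = ground_truth),
            class = "cohort")
}
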