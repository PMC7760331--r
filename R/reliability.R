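# Split-half reliability of per-trial dilation scores; feeds SEMs into the
# measurement-error correlation model.

#' Split-half reliability of per-trial scores
#'
#' Splits each subject's trials into two halves (default: first half vs
#' second half, i.e. trials 1-5 vs 6-10 for ten trials), averages each half
#' per subject, and correlates the half-means across subjects. The
#' Spearman-Brown adjustment 2r / (1 + r) is reported alongside the raw
#' correlation, never silently substituted.
#'
#' @param scores numeric matrix, subjects in rows, trials (in presentation
#'   order) in columns; `NA` marks trials discarded by QC.
#' @param scheme `"first_last"` (default) or `"odd_even"`.
#' @param min_per_half minimum number of non-missing trials a subject needs
#'   in each half; subjects below it are dropped (and recorded).
#' @return an object of class `reliability_estimate`: list with `method`,
#'   `r`, `r_adjusted`, `n_subjects`, `dropped_subjects`.
#' @export
split_half_reliability <- function(scores, scheme = c("first_last", "odd_even"),
                                   min_per_half = 1L) {
  scheme <- match.arg(scheme)
  scores <- as.matrix(scores)
  if (ncol(scores) < 4) stop("split_half_reliability: need >= 2 trials per half")
  idx <- seq_len(ncol(scores))
  in_first <- if (scheme == "first_last") idx <= ceiling(ncol(scores) / 2)
              else idx %% 2 == 1
  m1 <- rowMeans(scores[, in_first, drop = FALSE], na.rm = TRUE)
  m2 <- rowMeans(scores[, !in_first, drop = FALSE], na.rm = TRUE)
  n1 <- rowSums(!is.na(scores[, in_first, drop = FALSE]))
  n2 <- rowSums(!is.na(scores[, !in_first, drop = FALSE]))
  keep <- n1 >= min_per_half & n2 >= min_per_half
  dropped <- which(!keep)
  if (length(dropped))
    message("split_half_reliability: dropped ", length(dropped),
            " subject(s) with an empty half")
  if (sum(keep) < 4) stop("split_half_reliability: need >= 4 usable subjects")
  r <- pearson_r(m1[keep], m2[keep])
  structure(list(method = paste0("split_half_", scheme), r = r,
                 r_adjusted = 2 * r / (1 + r), n_subjects = sum(keep),
                 dropped_subjects = dropped),
            class = "reliability_estimate")
}

#' @export
print.reliability_estimate <- function(x, ...) {
  cat(sprintf("%s reliability: r = %.3f (Spearman-Brown: %.3f), n = %d\n",
              x$method, x$r, x$r_adjusted, x$n_subjects))
  invisible(x)
}

#' Convert a reliability estimate to a standard error of measurement
#'
#' Delegates to [sem_from_reliability()]; negative reliabilities are
#' rejected (a negative split-half correlation indicates the score carries
#' no stable between-subject signal, and no meaningful SEM exists).
#'
#' @param estimate a `reliability_estimate` or a plain correlation in
#'   \[0, 1\].
#' @param sd observed-score standard deviation.
#' @return the SEM.
#' @export
reliability_to_sem <- function(estimate, sd) {
  r <- if (inherits(estimate, "reliability_estimate")) estimate$r else estimate
  if (length(r) != 1L || !is.finite(r)) stop("reliability_to_sem: invalid r")
  if (r < 0)
    stop("reliability_to_sem: negative reliability (", sprintf("%.3f", r),
         "); the score has no stable between-subject signal, no SEM is defined")
  if (r > 1) stop("reliability_to_sem: reliability must be <= 1")
  sem_from_reliability(sd, r)
}

#' Per-condition split-half reliability table
#'
#' Computes [split_half_reliability()] separately for each condition from a
#' long table of kept per-trial dilation scores.
#'
#' @param trial_scores data.frame with columns `subject`, `condition`,
#'   `trial_index`, `score` (only kept trials; discarded trials absent or
#'   `NA`).
#' @param trials_per_condition number of trial columns per condition.
#' @param scheme passed to [split_half_reliability()].
#' @return data.frame with columns `condition`, `method`, `r`, `r_adjusted`,
#'   `n_subjects`.
#' @export
reliability_by_condition <- function(trial_scores, trials_per_condition = 10L,
                                     scheme = "first_last") {
  stopifnot(all(c("subject", "condition", "trial_index", "score") %in%
                  names(trial_scores)))
  out <- lapply(split(trial_scores, trial_scores$condition), function(d) {
    subjects <- sort(unique(d$subject))
    m <- matrix(NA_real_, length(subjects), trials_per_condition,
                dimnames = list(subjects, NULL))
    ok <- d$trial_index >= 1 & d$trial_index <= trials_per_condition
    m[cbind(match(d$subject[ok], subjects), d$trial_index[ok])] <- d$score[ok]
    est <- split_half_reliability(m, scheme = scheme)
    data.frame(condition = d$condition[1], method = est$method, r = est$r,
               r_adjusted = est$r_adjusted, n_subjects = est$n_subjects,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
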