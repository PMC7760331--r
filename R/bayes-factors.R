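# Default Bayes-factor machinery: Pearson correlation BF under a stretched
# beta prior, JZS two-sample t-test BF, partial correlations, evidence bands.

#' Gauss hypergeometric function 2F1 (series evaluation)
#'
#' Power-series evaluation of the Gauss hypergeometric function
#' \eqn{{}_2F_1(a, b; c; z)}, vectorised over `z`. Converges for `z` in
#' \[0, 1\] whenever `c - a - b > 0`, which is the regime needed by the exact
#' sampling density of the Pearson correlation (there `c` grows with `n`).
#'
#' @param a,b,c scalar parameters.
#' @param z numeric vector of arguments in \[0, 1\].
#' @param tol relative tolerance on the partial sums.
#' @param max_terms safety cap on the number of series terms.
#' @return numeric vector of the same length as `z`.
#' @keywords internal
gauss_2f1 <- function(a, b, c, z, tol = 1e-13, max_terms = 50000L) {
  stopifnot(is.numeric(z), all(z >= 0 & z <= 1))
  term <- rep(1, length(z))
  s <- rep(1, length(z))
  for (k in 0:(max_terms - 1L)) {
    term <- term * (a + k) * (b + k) / ((c + k) * (k + 1)) * z
    s <- s + term
    if (max(abs(term)) < tol * max(abs(s))) return(s)
  }
  stop("gauss_2f1: series did not converge (c - a - b too small?)")
}

#' Exact sampling density of the sample Pearson correlation
#'
#' Density of the sample correlation coefficient `r` computed from `n`
#' independent draws of a bivariate normal with population correlation `rho`
#' (Hotelling's rapidly converging hypergeometric form). Integrates to one
#' over (-1, 1).
#'
#' @param r evaluation point(s), in (-1, 1). Vectorised; recycled against
#'   `rho`.
#' @param rho population correlation in (-1, 1).
#' @param n sample size (>= 4).
#' @param log return the log density?
#' @return numeric vector of densities.
#' @examples
#' integrate(r_sampling_density, -1, 1, rho = 0.5, n = 20)  # ~1
#' @export
r_sampling_density <- function(r, rho, n, log = FALSE) {
  if (n < 4) stop("r_sampling_density: n must be >= 4")
  if (any(abs(r) >= 1)) stop("r_sampling_density: |r| must be < 1")
  if (any(abs(rho) >= 1)) stop("r_sampling_density: |rho| must be < 1")
  lc <- log(n - 2) + lgamma(n - 1) - 0.5 * log(2 * pi) - lgamma(n - 0.5)
  ld <- lc + ((n - 1) / 2) * log1p(-rho^2) + ((n - 4) / 2) * log1p(-r^2) -
    (n - 1.5) * log1p(-rho * r)
  ld <- ld + log(gauss_2f1(0.5, 0.5, n - 0.5, (rho * r + 1) / 2))
  if (log) ld else exp(ld)
}

#' Stretched beta prior on a correlation
#'
#' Prior specification for the Bayesian Pearson correlation test: a
#' Beta(1/width, 1/width) distribution linearly stretched from (0, 1) to
#' (-1, 1). Width 1 is the uniform prior on (-1, 1). One-sided variants
#' restrict and renormalise the prior to the requested half interval.
#'
#' @param width positive prior width (default 1).
#' @param sidedness one of `"two_sided"`, `"negative"` (rho < 0) or
#'   `"positive"` (rho > 0).
#' @return an object of class `correlation_prior`.
#' @export
correlation_prior <- function(width = 1,
                              sidedness = c("two_sided", "negative", "positive")) {
  sidedness <- match.arg(sidedness)
  if (!is.numeric(width) || length(width) != 1L || width <= 0)
    stop("correlation_prior: width must be a positive scalar")
  structure(list(width = width, sidedness = sidedness),
            class = "correlation_prior")
}

#' @export
print.correlation_prior <- function(x, ...) {
  cat(sprintf("stretched beta prior (width = %g, %s)\n", x$width, x$sidedness))
  invisible(x)
}

# prior density over the support implied by sidedness (renormalised)
stretched_beta_density <- function(rho, prior) {
  a <- 1 / prior$width
  d <- exp((a - 1) * log1p(-rho^2) - (2 * a - 1) * log(2) - lbeta(a, a))
  switch(prior$sidedness,
         two_sided = d,
         negative = ifelse(rho < 0, 2 * d, 0),
         positive = ifelse(rho > 0, 2 * d, 0))
}

#' Sample Pearson correlation
#'
#' @param x,y numeric vectors of equal length (n >= 3), each with nonzero
#'   variance.
#' @return the sample correlation, in \[-1, 1\].
#' @examples
#' pearson_r(c(1, 2, 3, 4), c(2, 1, 4, 3))  # 0.6
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("pearson_r: x and y must have equal length")
  if (length(x) < 3) stop("pearson_r: need at least 3 observations")
  if (anyNA(x) || anyNA(y)) stop("pearson_r: missing values not allowed")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("pearson_r: zero variance in x or y")
  stats::cor(x, y)
}

evidence_band_labels <- c(
  "extreme H0", "very strong H0", "strong H0", "moderate H0", "anecdotal H0",
  "anecdotal H1", "moderate H1", "strong H1", "very strong H1", "extreme H1")

#' Evidence band for a Bayes factor
#'
#' Maps BF10 onto the conventional evidence categories: (1, 3\] anecdotal,
#' (3, 10\] moderate, (10, 30\] strong, (30, 100\] very strong, > 100 extreme
#' evidence for H1; the reciprocal intervals mirror these for H0; BF10 = 1 is
#' labelled equivocal.
#'
#' @param bf10 positive Bayes factor(s) in favour of the alternative.
#' @return character vector of band labels.
#' @examples
#' classify_evidence(c(23.2, 1, 1/50))
#' @export
classify_evidence <- function(bf10) {
  if (any(!is.finite(bf10) & !is.infinite(bf10)) || any(bf10 <= 0, na.rm = TRUE))
    stop("classify_evidence: bf10 must be positive")
  cuts <- c(0, 1/100, 1/30, 1/10, 1/3, 1, 3, 10, 30, 100, Inf)
  lab <- evidence_band_labels[findInterval(bf10, cuts, left.open = TRUE)]
  lab[bf10 == 1] <- "equivocal"
  lab
}

new_evidence_result <- function(stat_type, statistic, n, bf10, prior,
                                extra = list()) {
  res <- c(list(stat_type = stat_type, statistic = statistic, n = n,
                bf10 = bf10, log10_bf10 = log10(bf10),
                band = classify_evidence(bf10), prior = prior), extra)
  structure(res, class = "evidence_result")
}

#' @export
print.evidence_result <- function(x, ...) {
  cat(sprintf("Bayesian %s test: %s = %.4f, n = %s\n",
              if (x$stat_type == "r") "correlation" else "t",
              x$stat_type, x$statistic,
              paste(x$n, collapse = " + ")))
  if (inherits(x$prior, "correlation_prior")) print(x$prior)
  else cat(sprintf("Cauchy prior scale = %g\n", x$prior))
  cat(sprintf("BF10 = %.4g (log10 = %.3f): %s evidence\n",
              x$bf10, x$log10_bf10, x$band))
  invisible(x)
}

#' Bayes factor for a Pearson correlation from sufficient statistics
#'
#' Default Bayesian correlation test computed from the sufficient statistics
#' (n, r): the marginal likelihood of the observed correlation under
#' \eqn{\rho \sim} stretched beta prior, divided by its likelihood under
#' \eqn{\rho = 0}, using the exact sampling density of the sample correlation
#' under bivariate normality. With the default width-1 (uniform) prior this
#' reproduces the standard two-sided default test.
#'
#' @param n sample size (>= 4).
#' @param r observed sample correlation, |r| < 1.
#' @param prior a [correlation_prior()].
#' @return an `evidence_result` with elements `statistic`, `n`, `bf10`,
#'   `log10_bf10`, `band` and the prior.
#' @examples
#' correlation_bf(66, -0.39)  # BF10 ~ 23-26, "strong H1"
#' @export
correlation_bf <- function(n, r, prior = correlation_prior()) {
  if (!inherits(prior, "correlation_prior"))
    stop("correlation_bf: prior must be a correlation_prior")
  if (n < 4) stop("correlation_bf: n must be >= 4")
  if (abs(r) >= 1) stop("correlation_bf: |r| must be < 1")
  integrand <- function(rho)
    stretched_beta_density(rho, prior) * r_sampling_density(r, rho, n)
  lims <- switch(prior$sidedness,
                 two_sided = c(-1, 1), negative = c(-1, 0), positive = c(0, 1))
  quad <- tryCatch(
    stats::integrate(function(v) vapply(v, integrand, numeric(1)),
                     lims[1], lims[2], rel.tol = 1e-9, abs.tol = 0,
                     subdivisions = 500L),
    error = function(e) stop("correlation_bf: quadrature failed (n = ", n,
                             ", r = ", r, "): ", conditionMessage(e)))
  if (quad$message != "OK")
    stop("correlation_bf: quadrature did not converge: ", quad$message)
  bf10 <- quad$value / r_sampling_density(r, 0, n)
  new_evidence_result("r", r, n, bf10, prior)
}

#' Bayes factor for a Pearson correlation from raw data
#'
#' Vector interface wrapping [correlation_bf()]: computes the sample
#' correlation with [pearson_r()] and evaluates the sufficient-statistic test.
#'
#' @inheritParams pearson_r
#' @inheritParams correlation_bf
#' @export
correlation_bf_xy <- function(x, y, prior = correlation_prior()) {
  correlation_bf(length(x), pearson_r(x, y), prior)
}

#' JZS Bayes factor for an independent-samples t test
#'
#' Default Bayesian two-sample t test: the observed t statistic is modelled
#' with a noncentral t likelihood whose noncentrality is
#' \eqn{\delta \sqrt{n_1 n_2 / (n_1 + n_2)}}, with a Cauchy prior on the
#' standardised effect size \eqn{\delta} (the variance nuisance is absorbed
#' into the t likelihood). BF10 is the prior-marginal likelihood divided by
#' the likelihood at \eqn{\delta = 0}, by adaptive quadrature over
#' \eqn{\delta}.
#'
#' Either pass the t statistic and group sizes, or two raw data vectors
#' (pooled-variance t test computed internally).
#'
#' @param t observed t statistic (ignored if `x` and `y` are given).
#' @param n1,n2 group sizes (each >= 2).
#' @param x,y optional raw data vectors.
#' @param cauchy_scale scale of the Cauchy prior on effect size (default 0.7).
#' @return an `evidence_result` (element `n` holds `c(n1, n2)`).
#' @examples
#' jzs_ttest_bf(t = 3, n1 = 30, n2 = 30)
#' @export
jzs_ttest_bf <- function(t = NULL, n1 = NULL, n2 = NULL, x = NULL, y = NULL,
                         cauchy_scale = 0.7) {
  if (!is.null(x) || !is.null(y)) {
    if (is.null(x) || is.null(y)) stop("jzs_ttest_bf: need both x and y")
    n1 <- length(x); n2 <- length(y)
    if (n1 < 2 || n2 < 2) stop("jzs_ttest_bf: each group needs n >= 2")
    sp2 <- ((n1 - 1) * stats::var(x) + (n2 - 1) * stats::var(y)) / (n1 + n2 - 2)
    if (sp2 <= 0) stop("jzs_ttest_bf: degenerate (zero) pooled variance")
    t <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  }
  if (is.null(t) || is.null(n1) || is.null(n2))
    stop("jzs_ttest_bf: supply either t, n1, n2 or raw data x, y")
  if (n1 < 2 || n2 < 2) stop("jzs_ttest_bf: each group needs n >= 2")
  if (!is.finite(t)) stop("jzs_ttest_bf: t is not finite (degenerate variance?)")
  if (cauchy_scale <= 0) stop("jzs_ttest_bf: cauchy_scale must be positive")
  df <- n1 + n2 - 2
  neff <- sqrt(n1 * n2 / (n1 + n2))
  marg <- suppressWarnings(stats::integrate(
    function(d) stats::dcauchy(d, 0, cauchy_scale) * stats::dt(t, df, ncp = d * neff),
    -Inf, Inf, rel.tol = 1e-8))
  if (marg$message != "OK")
    stop("jzs_ttest_bf: quadrature did not converge: ", marg$message)
  bf10 <- marg$value / stats::dt(t, df)
  new_evidence_result("t", t, c(n1, n2), bf10, cauchy_scale)
}

#' Bayes factor for a partial correlation
#'
#' Residualises `x` and `y` on the covariates (plus an intercept) by least
#' squares, correlates the residuals, and evaluates [correlation_bf()] with
#' the effective sample size reduced by the number of covariates. This is a
#' residualisation approximation to a fully Bayesian partial-correlation
#' test.
#'
#' @param x,y numeric vectors.
#' @param covariates numeric matrix or data.frame of covariates (columns may
#'   be factors; they are expanded via `model.matrix`).
#' @param prior a [correlation_prior()].
#' @return an `evidence_result`; the extra element `n_covariates` records the
#'   adjustment.
#' @export
partial_correlation_bf <- function(x, y, covariates,
                                   prior = correlation_prior()) {
  covariates <- as.data.frame(covariates)
  n <- length(x)
  if (length(y) != n || nrow(covariates) != n)
    stop("partial_correlation_bf: x, y and covariates must have equal length")
  mm <- stats::model.matrix(~ ., data = covariates)
  k <- ncol(mm) - 1L
  if (n <= k + 3) stop("partial_correlation_bf: n must exceed #covariates + 3")
  if (qr(mm)$rank < ncol(mm))
    stop("partial_correlation_bf: rank-deficient covariate matrix")
  rx <- stats::lm.fit(mm, x)$residuals
  ry <- stats::lm.fit(mm, y)$residuals
  if (stats::sd(rx) < 1e-12 || stats::sd(ry) < 1e-12)
    stop("partial_correlation_bf: zero residual variance (variable collinear with covariates)")
  res <- correlation_bf(n - k, pearson_r(rx, ry), prior)
  res$n_covariates <- k
  res$n_raw <- n
  res
}

#' Tabulate evidence results
#'
#' Collapses a list of `evidence_result` objects into one data.frame row per
#' result, suitable for writing as delimited text.
#'
#' @param results list of `evidence_result` objects (possibly named).
#' @return a data.frame with columns `label`, `stat_type`, `statistic`, `n`,
#'   `prior`, `bf10`, `log10_bf10`, `band`.
#' @export
evidence_table <- function(results) {
  stopifnot(all(vapply(results, inherits, logical(1), "evidence_result")))
  labs <- names(results)
  if (is.null(labs)) labs <- paste0("test_", seq_along(results))
  do.call(rbind, lapply(seq_along(results), function(i) {
    r <- results[[i]]
    data.frame(
      label = labs[i], stat_type = r$stat_type,
      statistic = r$statistic, n = paste(r$n, collapse = "+"),
      prior = if (inherits(r$prior, "correlation_prior"))
        sprintf("stretched_beta(width=%g,%s)", r$prior$width, r$prior$sidedness)
      else sprintf("cauchy(scale=%g)", r$prior),
      bf10 = r$bf10, log10_bf10 = r$log10_bf10, band = r$band,
      stringsAsFactors = FALSE)
  }))
}
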