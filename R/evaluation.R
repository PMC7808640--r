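#' Per-sample mean absolute error
#'
#' For each sample `s`, the mean over genes of `|y(g,s) - yhat(g,s)|`.
#' Samples are treated as the independent replication unit throughout the
#' model-comparison machinery, because genes within a sample are strongly
#' dependent while samples are (approximately) exchangeable.
#'
#' @param truth,prediction Samples-by-genes numeric matrices of equal shape.
#' @return Numeric vector with one MAE per sample.
#' @export
mae_per_sample <- function(truth, prediction) {
  if (!all(dim(truth) == dim(prediction))) {
    stop_dimension("truth and prediction shapes differ")
  }
  rowMeans(abs(truth - prediction))
}

#' Overall model error (MMAE)
#'
#' The mean over samples of the per-sample MAE.
#'
#' @param per_sample_mae Non-empty numeric vector from [mae_per_sample()].
#' @return Scalar MMAE.
#' @export
mmae <- function(per_sample_mae) {
  if (length(per_sample_mae) == 0) stop_argument("empty per-sample MAE vector")
  mean(per_sample_mae)
}

#' Per-sample mean difference of absolute errors
#'
#' For each sample, the mean over genes of `|y - yhat_m1| - |y - yhat_m2|`;
#' identically the difference of the two models' per-sample MAEs.  Negative
#' values favor model 1.
#'
#' @param truth,pred_m1,pred_m2 Samples-by-genes matrices of equal shape.
#' @return Numeric vector with one MDAE per sample.
#' @export
mdae_per_sample <- function(truth, pred_m1, pred_m2) {
  if (!all(dim(truth) == dim(pred_m1)) || !all(dim(truth) == dim(pred_m2))) {
    stop_dimension("matrix shapes differ")
  }
  rowMeans(abs(truth - pred_m1) - abs(truth - pred_m2))
}

#' Overall mean difference of absolute errors (MMDAE)
#'
#' The mean over samples of [mdae_per_sample()]; equals
#' `mmae(m1) - mmae(m2)` and is antisymmetric in the two models.
#'
#' @inheritParams mdae_per_sample
#' @return Scalar MMDAE (negative favors model 1).
#' @export
mmdae <- function(truth, pred_m1, pred_m2) {
  mean(mdae_per_sample(truth, pred_m1, pred_m2))
}

#' Percentile bootstrap confidence interval for a mean
#'
#' Resamples the value vector with replacement `n_bootstrap` times,
#' computes the mean of each resample, and returns the percentile interval
#' whose endpoints are order statistics of the resampled means (the
#' `ceiling(B * p)`-th sorted value at probability `p`).  Deterministic
#' under the seed.
#'
#' @param per_sample_values Non-empty numeric vector (e.g. per-sample MAEs
#'   or MDAEs).
#' @param n_bootstrap Number of bootstrap resamples (>= 1).
#' @param level Interval coverage level (default 0.95).
#' @param seed Integer seed.
#' @return Named numeric `c(low, high)`.
#' @export
bootstrap_ci <- function(per_sample_values, n_bootstrap = 1000,
                         level = 0.95, seed = 1) {
  n <- length(per_sample_values)
  if (n == 0) stop_argument("empty value vector")
  if (!is_count(n_bootstrap)) stop_argument("n_bootstrap must be >= 1")
  means <- with_seed(seed, {
    idx <- matrix(sample.int(n, n * n_bootstrap, replace = TRUE), nrow = n)
    colMeans(matrix(per_sample_values[idx], nrow = n))
  })
  s <- sort(means)
  p_lo <- (1 - level) / 2
  p_hi <- 1 - p_lo
  # inverse-ECDF order statistic; the fuzz keeps B*p at its exact integer
  # when (1-level)/2 picks up float noise
  pick <- function(p) s[min(n_bootstrap, max(1L, ceiling(n_bootstrap * p - 1e-9)))]
  c(low = pick(p_lo), high = pick(p_hi))
}

#' Paired significance tests on per-sample errors
#'
#' Two-sided paired Student t-test and Wilcoxon signed-rank test on the
#' per-sample differences `m1 - m2`.  Conventions for the signed-rank test:
#' zero differences are dropped (Wilcoxon's original treatment); the exact
#' distribution is used for up to 25 non-zero differences (falling back to
#' the normal approximation when ties make the exact distribution
#' unavailable), and the tie/continuity-corrected normal approximation
#' beyond that.  Degenerate inputs are defined, not fatal: all-zero
#' differences give p = 1 for both tests with a warning, and a non-zero
#' mean difference with zero variance gives t-test p = 0 with a warning.
#'
#' @param mae_m1,mae_m2 Equal-length numeric vectors (length >= 2).
#' @return Named numeric `c(t_p, wilcoxon_p)`.
#' @export
paired_tests <- function(mae_m1, mae_m2) {
  if (length(mae_m1) != length(mae_m2)) stop_dimension("vector lengths differ")
  if (length(mae_m1) < 2) stop_argument("need at least 2 paired values")
  d <- mae_m1 - mae_m2
  if (all(d == 0)) {
    warning("all paired differences are zero; tests are uninformative (p = 1)")
    return(c(t_p = 1, wilcoxon_p = 1))
  }
  stderr_d <- stats::sd(d) / sqrt(length(d))
  if (stderr_d <= 10 * .Machine$double.eps * abs(mean(d))) {
    # same guard stats::t.test applies: the difference is constant to
    # machine precision, so a non-zero mean is a certainty
    warning("paired differences have zero variance with non-zero mean; t-test p set to 0")
    t_p <- 0
  } else {
    t_p <- stats::t.test(mae_m1, mae_m2, paired = TRUE)$p.value
  }
  dz <- d[d != 0]
  if (length(dz) > 25) {
    w <- stats::wilcox.test(dz, exact = FALSE, correct = TRUE)
  } else {
    w <- suppressWarnings(stats::wilcox.test(dz, exact = TRUE))
  }
  c(t_p = t_p, wilcoxon_p = w$p.value)
}

#' Full pairwise model comparison
#'
#' Computes the MMDAE point estimate for a model pair, its percentile
#' bootstrap confidence interval over samplewise MDAEs, and the paired
#' t-test and Wilcoxon signed-rank p-values over samplewise MAEs — the
#' complete comparison reported for every model pair.
#'
#' @param truth Samples-by-genes ground-truth matrix.
#' @param pred_m1,pred_m2 Prediction matrices of the two models.
#' @param model_ids Length-2 character vector naming the models.
#' @param n_bootstrap,level,seed Bootstrap settings (see [bootstrap_ci()]).
#' @return A one-row tibble of class `model_comparison` with columns
#'   `model_1`, `model_2`, `mmdae`, `ci_low`, `ci_high`, `t_test_p`,
#'   `wilcoxon_p`, `n_bootstrap`, `seed`.  Negative `mmdae` favors
#'   `model_1`.
#' @export
compare_models <- function(truth, pred_m1, pred_m2,
                           model_ids = c("m1", "m2"),
                           n_bootstrap = 1000, level = 0.95, seed = 1) {
  mdae <- mdae_per_sample(truth, pred_m1, pred_m2)
  ci <- bootstrap_ci(mdae, n_bootstrap = n_bootstrap, level = level,
                     seed = seed)
  tests <- paired_tests(mae_per_sample(truth, pred_m1),
                        mae_per_sample(truth, pred_m2))
  out <- tibble::tibble(
    model_1 = model_ids[1], model_2 = model_ids[2],
    mmdae = mean(mdae), ci_low = ci[["low"]], ci_high = ci[["high"]],
    t_test_p = tests[["t_p"]], wilcoxon_p = tests[["wilcoxon_p"]],
    n_bootstrap = as.integer(n_bootstrap), seed = as.integer(seed)
  )
  class(out) <- c("model_comparison", class(out))
  out
}

#' Write a comparison report as a tab-delimited table
#'
#' @param report A [compare_models()] result (rows may be bound together).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_comparison <- function(report, path) {
  utils::write.table(as.data.frame(report), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
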