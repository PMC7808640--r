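#' Artificial two-class phenotypes by hierarchical clustering
#'
#' When no phenotype annotation exists, two classes with naturally distinct
#' expression profiles are introduced by agglomerative clustering (Ward
#' linkage on Euclidean distances) of a seeded random subset of samples:
#' the tree is cut at the shallowest level at which the two largest
#' clusters both exceed `min_cluster` samples, and those two clusters
#' become the classes; remaining samples stay unlabeled.
#'
#' @param expression Samples-by-genes numeric matrix with sample ids as
#'   rownames.
#' @param n_samples Size of the random subset to cluster (default 2000).
#' @param min_cluster Minimum size required of both clusters (default 300).
#' @param seed Integer seed.
#' @return Named character vector of labels `"A"`/`"B"` over the samples in
#'   the two selected clusters (`"A"` is the larger cluster).
#' @export
artificial_phenotypes <- function(expression, n_samples = 2000,
                                  min_cluster = 300, seed = 1) {
  if (nrow(expression) < n_samples) {
    stop_argument("expression has fewer samples than n_samples")
  }
  if (2 * min_cluster > n_samples) {
    stop_infeasible("min_cluster exceeds half the clustered samples; two such clusters cannot exist")
  }
  rows <- with_seed(seed, sort(sample(rownames(expression), n_samples)))
  sub <- expression[rows, , drop = FALSE]
  hc <- stats::hclust(stats::dist(sub), method = "ward.D2")
  for (k in 2:(n_samples - 1)) {
    ct <- stats::cutree(hc, k = k)
    sizes <- sort(table(ct), decreasing = TRUE)
    if (length(sizes) >= 2 && sizes[2] >= min_cluster) {
      top2 <- as.integer(names(sizes)[1:2])
      labels <- stats::setNames(rep(NA_character_, length(ct)), names(ct))
      labels[ct == top2[1]] <- "A"
      labels[ct == top2[2]] <- "B"
      return(labels[!is.na(labels)])
    }
    # once the second-largest cluster falls below the threshold further cuts
    # only fragment more; but sizes are not monotone in k, so keep scanning
  }
  stop_infeasible("no cut yields two clusters of the required size")
}

# vectorized Welch two-sample t-test over gene columns
welch_t_pvalues <- function(expression, labels) {
  classes <- sort(unique(labels))
  x1 <- expression[labels == classes[1], , drop = FALSE]
  x2 <- expression[labels == classes[2], , drop = FALSE]
  n1 <- nrow(x1); n2 <- nrow(x2)
  m1 <- colMeans(x1); m2 <- colMeans(x2)
  v1 <- colSums(sweep(x1, 2, m1)^2) / (n1 - 1)
  v2 <- colSums(sweep(x2, 2, m2)^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  p <- numeric(length(m1))
  zero <- se2 == 0
  # zero variance in both classes: identical means are uninformative (p = 1),
  # different means are a certain difference (p = 0)
  p[zero] <- ifelse(m1[zero] == m2[zero], 1, 0)
  ok <- !zero
  tstat <- (m1[ok] - m2[ok]) / sqrt(se2[ok])
  df <- se2[ok]^2 / (v1[ok]^2 / (n1^2 * (n1 - 1)) + v2[ok]^2 / (n2^2 * (n2 - 1)))
  p[ok] <- 2 * stats::pt(-abs(tstat), df)
  stats::setNames(p, colnames(expression))
}

# limma empirical-Bayes moderated t-test backend
limma_pvalues <- function(expression, labels) {
  if (!requireNamespace("limma", quietly = TRUE)) {
    stop_argument("the limma backend requires the limma package")
  }
  design <- stats::model.matrix(~ factor(labels))
  fit <- limma::eBayes(limma::lmFit(t(expression), design))
  stats::setNames(fit$p.value[, 2], colnames(expression))
}

#' Differential-expression calling
#'
#' Per-gene two-class tests with Benjamini-Hochberg adjustment; genes with
#' adjusted p below `alpha_adj` are flagged differentially expressed.  The
#' test backend is pluggable: the default is a Welch two-sample t-test; the
#' `"limma"` backend uses the moderated empirical-Bayes t-test; or supply
#' any `function(expression, labels)` returning a per-gene p-value vector.
#'
#' @param expression Samples-by-genes numeric matrix.
#' @param labels Two-class label vector over samples (each class needs at
#'   least 2 samples); a named vector is aligned to the matrix rows.
#' @param alpha_adj Adjusted-p threshold for the DE flag (default 0.01).
#' @param backend `"welch"`, `"limma"`, or a p-value function.
#' @return A tibble with columns `gene_id`, `p`, `p_adj`, `de` (ordered as
#'   the input genes).
#' @export
call_de <- function(expression, labels, alpha_adj = 0.01,
                    backend = c("welch", "limma")) {
  if (!is.null(names(labels))) {
    if (!all(rownames(expression) %in% names(labels))) {
      stop_dimension("labels must cover every sample in the matrix")
    }
    labels <- labels[rownames(expression)]
  }
  if (length(labels) != nrow(expression)) {
    stop_dimension("labels must have one entry per sample")
  }
  classes <- sort(unique(labels))
  if (length(classes) != 2) stop_argument("labels must define exactly two classes")
  if (min(table(labels)) < 2) stop_argument("each class needs at least 2 samples")
  fn <- if (is.function(backend)) backend
        else switch(match.arg(backend), welch = welch_t_pvalues,
                    limma = limma_pvalues)
  p <- fn(expression, labels)
  p_adj <- stats::p.adjust(p, method = "BH")
  tibble::tibble(gene_id = colnames(expression), p = as.numeric(p),
                 p_adj = as.numeric(p_adj), de = p_adj < alpha_adj)
}

#' Confusion-matrix scores for DE recovery
#'
#' Accuracy, the F-beta family and the Matthews correlation coefficient of
#' predicted DE flags against reference flags:
#' `F_beta = (1 + beta^2) P R / (beta^2 P + R)` with precision
#' `P = TP/(TP+FP)` and recall `R = TP/(TP+FN)`, and
#' `MCC = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`.
#' Degenerate denominators yield a score of 0 with a warning.
#'
#' @param truth_flags,predicted_flags Equal-length logical vectors.
#' @param betas F-score beta values (default `c(0.5, 1, 2)`).
#' @return Named numeric: `accuracy`, `f_<beta>` per beta, `mcc`.
#' @export
confusion_scores <- function(truth_flags, predicted_flags,
                             betas = c(0.5, 1, 2)) {
  if (length(truth_flags) != length(predicted_flags)) {
    stop_dimension("flag vector lengths differ")
  }
  tp <- sum(truth_flags & predicted_flags)
  fp <- sum(!truth_flags & predicted_flags)
  fn <- sum(truth_flags & !predicted_flags)
  tn <- sum(!truth_flags & !predicted_flags)
  acc <- (tp + tn) / length(truth_flags)
  warn_degenerate <- FALSE
  prec <- if (tp + fp > 0) tp / (tp + fp) else { warn_degenerate <- TRUE; NA }
  rec <- if (tp + fn > 0) tp / (tp + fn) else { warn_degenerate <- TRUE; NA }
  fbeta <- vapply(betas, function(b) {
    if (is.na(prec) || is.na(rec) || (b^2 * prec + rec) == 0) {
      warn_degenerate <<- TRUE
      0
    } else {
      (1 + b^2) * prec * rec / (b^2 * prec + rec)
    }
  }, numeric(1))
  denom <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  mcc <- if (denom > 0) {
    (tp * tn - fp * fn) / sqrt(denom)
  } else {
    warn_degenerate <- TRUE
    0
  }
  if (warn_degenerate) {
    warning("degenerate confusion matrix: some scores set to 0")
  }
  out <- c(accuracy = acc,
           stats::setNames(fbeta, paste0("f_", sub("\\.?0+$", "", format(betas)))),
           mcc = mcc)
  out
}

# 1-based significance ranks: ascending p, ties broken by gene id
significance_ranks <- function(p) {
  ids <- names(p)
  ord <- order(p, ids)
  stats::setNames(seq_along(p)[order(ord)], ids)[ids]
}

#' Rank agreement of DE candidate lists
#'
#' Candidate genes are selected on the *truth* ordering — either the `k`
#' most significant genes or all genes with truth p below `alpha` — and the
#' mean absolute difference between each candidate's rank in the truth
#' ordering and its rank in the inferred ordering is returned.  Ranks are
#' 1-based, ordered by ascending p-value with ties broken by gene id.
#'
#' @param truth_p,inferred_p Named per-gene p-value vectors over the same
#'   gene universe.
#' @param selection `"top_k"` or `"p_threshold"`.
#' @param k Candidate count for `"top_k"` (default 100).
#' @param alpha Significance level for `"p_threshold"` (default 0.05).
#' @return Mean absolute rank difference over candidates; `NA` with a
#'   warning when the p-threshold selection is empty.
#' @export
rank_agreement <- function(truth_p, inferred_p,
                           selection = c("top_k", "p_threshold"),
                           k = 100, alpha = 0.05) {
  selection <- match.arg(selection)
  if (!setequal(names(truth_p), names(inferred_p))) {
    stop_schema("orderings cover different gene universes")
  }
  truth_rank <- significance_ranks(truth_p)
  inferred_rank <- significance_ranks(inferred_p)[names(truth_rank)]
  candidates <- if (selection == "top_k") {
    names(truth_rank)[truth_rank <= min(k, length(truth_rank))]
  } else {
    names(truth_p)[truth_p < alpha]
  }
  if (length(candidates) == 0) {
    warning("empty candidate set under the p-threshold selection")
    return(NA_real_)
  }
  mean(abs(truth_rank[candidates] - inferred_rank[candidates]))
}

#' Repeated balanced-subsample DGE evaluation
#'
#' Measures how faithfully DE analysis on inferred expression reproduces DE
#' analysis on ground-truth expression across small-study sample sizes.
#' For each size `s` and repetition, a balanced subsample (`s/2` per class)
#' is drawn; DE is called on the ground truth and on every inferred matrix
#' restricted to the same samples; confusion scores take the truth DE flags
#' as reference, and rank agreement compares significance orderings (top-k
#' and p-threshold candidate selections).  Per-repetition score differences
#' between each method pair are tested with the paired Wilcoxon signed-rank
#' test at each size.
#'
#' @param truth Samples-by-genes ground-truth matrix (or an
#'   [expression_dataset()], whose target matrix is used).
#' @param inferred Named list of samples-by-genes inferred matrices.
#' @param labels Two-class label vector (named by sample id).
#' @param sizes Integer vector of total subsample sizes (must be even).
#' @param repetitions Repetitions per size.
#' @param seed Integer seed; the whole experiment is deterministic.
#' @param alpha_adj DE-flag threshold (see [call_de()]).
#' @param backend DE backend (see [call_de()]).
#' @param k,alpha_rank Candidate-selection settings for [rank_agreement()].
#' @return Object of class `dge_eval`: list with `results` (long tibble:
#'   `method`, `size`, `repetition`, `metric`, `value`) and `tests`
#'   (tibble: `size`, `metric`, `method_1`, `method_2`, `wilcoxon_p`).
#' @export
subsample_experiment <- function(truth, inferred, labels, sizes = c(12, 60),
                                 repetitions = 200, seed = 1,
                                 alpha_adj = 0.01, backend = "welch",
                                 k = 100, alpha_rank = 0.05) {
  if (inherits(truth, "expression_dataset")) truth <- target_matrix(truth)
  if (is.null(names(labels))) {
    stop_argument("labels must be named by sample id")
  }
  labels <- labels[!is.na(labels)]
  classes <- sort(unique(labels))
  if (length(classes) != 2) stop_argument("labels must define exactly two classes")
  ids_by_class <- split(names(labels), labels)
  methods <- names(inferred)
  score_names <- c("accuracy", "f_0.5", "f_1", "f_2", "mcc",
                   "rank_mae_top100", "rank_mae_p05")
  rows <- list()
  with_seed(seed, {
    for (s in sizes) {
      half <- s %/% 2
      if (any(lengths(ids_by_class) < half)) {
        warning(sprintf("size %d skipped: a class has fewer than %d samples",
                        s, half))
        next
      }
      for (rep_i in seq_len(repetitions)) {
        take <- c(sample(ids_by_class[[1]], half),
                  sample(ids_by_class[[2]], half))
        lab <- labels[take]
        truth_de <- call_de(truth[take, , drop = FALSE], lab,
                            alpha_adj = alpha_adj, backend = backend)
        truth_p <- stats::setNames(truth_de$p, truth_de$gene_id)
        for (m in methods) {
          m_de <- call_de(inferred[[m]][take, , drop = FALSE], lab,
                          alpha_adj = alpha_adj, backend = backend)
          cs <- suppressWarnings(confusion_scores(truth_de$de, m_de$de))
          m_p <- stats::setNames(m_de$p, m_de$gene_id)
          r100 <- rank_agreement(truth_p, m_p, "top_k", k = k)
          rp <- suppressWarnings(
            rank_agreement(truth_p, m_p, "p_threshold", alpha = alpha_rank))
          vals <- c(unname(cs), r100, rp)
          rows[[length(rows) + 1L]] <- tibble::tibble(
            method = m, size = s, repetition = rep_i,
            metric = score_names, value = vals)
        }
      }
    }
  })
  results <- dplyr::bind_rows(rows)
  tests <- dge_wilcoxon_table(results)
  structure(list(results = results, tests = tests,
                 sizes = sizes, repetitions = repetitions, seed = seed),
            class = "dge_eval")
}

# paired Wilcoxon signed-rank tests between every method pair, per size and
# metric, over per-repetition score differences
dge_wilcoxon_table <- function(results) {
  methods <- sort(unique(results$method))
  if (length(methods) < 2 || nrow(results) == 0) {
    return(tibble::tibble(size = integer(), metric = character(),
                          method_1 = character(), method_2 = character(),
                          wilcoxon_p = numeric()))
  }
  pairs <- utils::combn(methods, 2, simplify = FALSE)
  wide <- tidyr::pivot_wider(results, names_from = "method",
                             values_from = "value")
  out <- list()
  for (s in unique(wide$size)) {
    for (met in unique(wide$metric)) {
      block <- wide[wide$size == s & wide$metric == met, ]
      for (pr in pairs) {
        d1 <- block[[pr[1]]]; d2 <- block[[pr[2]]]
        ok <- is.finite(d1) & is.finite(d2)
        p <- if (sum(ok) >= 2 && any(d1[ok] != d2[ok])) {
          suppressWarnings(
            stats::wilcox.test(d1[ok], d2[ok], paired = TRUE)$p.value)
        } else NA_real_
        out[[length(out) + 1L]] <- tibble::tibble(
          size = s, metric = met, method_1 = pr[1], method_2 = pr[2],
          wilcoxon_p = p)
      }
    }
  }
  dplyr::bind_rows(out)
}

#' @export
print.dge_eval <- function(x, ...) {
  cat(sprintf(
    "<dge_eval: %d methods, sizes {%s}, %d repetitions>\n",
    length(unique(x$results$method)),
    paste(sort(unique(x$results$size)), collapse = ", "),
    x$repetitions))
  invisible(x)
}

#' Write DGE evaluation tables as tab-delimited text
#'
#' @param x A [subsample_experiment()] result.
#' @param results_path,tests_path Output files for the long results table
#'   and the Wilcoxon summary.
#' @return Invisibly, the two paths.
#' @export
write_dge_eval <- function(x, results_path, tests_path) {
  utils::write.table(as.data.frame(x$results), results_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(as.data.frame(x$tests), tests_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(c(results_path, tests_path))
}
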