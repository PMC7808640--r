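test_that("clustering recovers planted well-separated phenotype blobs exactly", {
  withr::local_seed(2)
  n_per <- 300; d <- 5
  blob <- rbind(matrix(rnorm(n_per * d), n_per, d),
                matrix(rnorm(n_per * d, mean = 10), n_per, d))
  rownames(blob) <- sprintf("s%03d", seq_len(2 * n_per))
  truth_class <- rep(c("one", "two"), each = n_per)
  labels <- artificial_phenotypes(blob, n_samples = 600, min_cluster = 250,
                                  seed = 3)
  expect_length(labels, 600)
  agree <- table(labels, truth_class[match(names(labels), rownames(blob))])
  # exact recovery up to label swap
  expect_equal(min(max(agree["A", ]), max(agree["B", ])) +
                 abs(sum(agree) - 600), 300)
  expect_identical(labels,
                   artificial_phenotypes(blob, 600, 250, seed = 3))
  expect_error(artificial_phenotypes(blob, 600, 301, seed = 1),
               class = "taafgex_infeasibility_error")
  expect_error(artificial_phenotypes(blob[1:10, ], 600, 10, seed = 1),
               class = "taafgex_argument_error")
})

test_that("the Welch backend agrees with stats::t.test gene by gene", {
  withr::local_seed(4)
  expr <- matrix(rnorm(40 * 20), 40, 20,
                 dimnames = list(sprintf("s%d", 1:40), sprintf("g%d", 1:20)))
  labels <- rep(c("A", "B"), each = 20)
  p <- taafgex:::welch_t_pvalues(expr, labels)
  for (g in 1:20) {
    ref <- t.test(expr[labels == "A", g], expr[labels == "B", g])$p.value
    expect_equal(unname(p[g]), ref, tolerance = 1e-12)
  }
  # degenerate genes: zero variance in both classes
  expr[, 1] <- 1                          # equal means -> p = 1
  expr[, 2] <- rep(c(0, 1), each = 20)    # different means -> p = 0
  p2 <- taafgex:::welch_t_pvalues(expr, labels)
  expect_equal(unname(p2[1:2]), c(1, 0))
})

test_that("DE calling controls type-I error under the null and respects BH", {
  withr::local_seed(6)
  expr <- matrix(rnorm(40 * 2000), 40, 2000,
                 dimnames = list(sprintf("s%d", 1:40), sprintf("g%d", 1:2000)))
  labels <- setNames(rep(c("A", "B"), each = 20), rownames(expr))
  de <- call_de(expr, labels, alpha_adj = 0.01)
  expect_gte(mean(de$p < 0.05), 0.03)
  expect_lte(mean(de$p < 0.05), 0.07)
  # BH adjustment: monotone non-decreasing in raw-p order and >= raw p
  ord <- order(de$p)
  expect_true(all(diff(de$p_adj[ord]) >= -1e-15))
  expect_true(all(de$p_adj >= de$p - 1e-15))
  expect_error(call_de(expr, labels[1:10]), class = "taafgex_dimension_error")
  expect_error(call_de(expr[1:3, ], setNames(c("A", "A", "B"),
                                             rownames(expr)[1:3])),
               class = "taafgex_argument_error")
})

test_that("the limma backend flags the same planted genes as the default", {
  cfg <- generator_config(n_samples = 200, n_landmarks = 5, n_targets = 100,
                          noise_sd = 0.3, series_effect_sd = 0,
                          n_de_genes = 8, de_effect_size = 1.5, seed = 11)
  out <- generate_phenotype_dataset(cfg)
  expr <- target_matrix(out$dataset)
  de_w <- call_de(expr, out$dataset$phenotype, backend = "welch")
  de_l <- call_de(expr, out$dataset$phenotype, backend = "limma")
  planted <- names(out$truth$de_flags)[out$truth$de_flags]
  expect_true(all(planted %in% de_w$gene_id[de_w$de]))
  expect_true(all(planted %in% de_l$gene_id[de_l$de]))
  expect_gt(cor(-log10(de_w$p), -log10(de_l$p)), 0.95)
  # a user-supplied backend function is honored
  de_fn <- call_de(expr, out$dataset$phenotype,
                   backend = function(e, l) taafgex:::welch_t_pvalues(e, l))
  expect_identical(de_fn$p, de_w$p)
})

test_that("confusion scores match the brute-force 2x2 computation", {
  # the canonical worked case: TP=2, FP=1, FN=1, TN=6
  truth <- c(TRUE, TRUE, TRUE, rep(FALSE, 7))
  pred <- c(TRUE, TRUE, FALSE, TRUE, rep(FALSE, 6))
  s <- confusion_scores(truth, pred)
  expect_equal(s[["f_1"]], 2 / 3)
  expect_equal(s[["accuracy"]], 0.8)
  expect_equal(s[["mcc"]], 11 / 21)
  # P = 1, R = 0.5 closed forms
  truth2 <- c(TRUE, TRUE, FALSE, FALSE)
  pred2 <- c(TRUE, FALSE, FALSE, FALSE)
  s2 <- confusion_scores(truth2, pred2)
  expect_equal(s2[["f_0.5"]], 1.25 * 0.5 / (0.25 + 0.5))
  expect_equal(s2[["f_2"]], 5 * 0.5 / (4 + 0.5))
  # perfect prediction
  sp <- confusion_scores(c(TRUE, FALSE), c(TRUE, FALSE))
  expect_true(all(sp == 1))
  # randomized brute-force agreement incl. the F1 harmonic-mean identity
  withr::local_seed(13)
  for (i in 1:100) {
    t0 <- runif(30) < 0.4; p0 <- runif(30) < 0.4
    s0 <- suppressWarnings(confusion_scores(t0, p0))
    b <- brute_confusion(t0, p0)
    expect_equal(s0[["accuracy"]], b$accuracy)
    if (is.finite(b$fbeta)) {
      expect_equal(s0[["f_1"]], b$fbeta)
      P <- b$table[["tp"]] / (b$table[["tp"]] + b$table[["fp"]])
      R <- b$table[["tp"]] / (b$table[["tp"]] + b$table[["fn"]])
      if (P > 0 && R > 0) expect_equal(s0[["f_1"]], 2 / (1 / P + 1 / R))
    }
    if (is.finite(b$mcc)) expect_equal(s0[["mcc"]], b$mcc)
  }
  expect_warning(confusion_scores(c(FALSE, FALSE), c(FALSE, FALSE)),
                 "degenerate")
  expect_error(confusion_scores(TRUE, c(TRUE, FALSE)),
               class = "taafgex_dimension_error")
})

test_that("rank agreement measures candidate displacement on truth-selected genes", {
  p <- setNames(c(0.001, 0.002, 0.003, 0.5, 0.6), sprintf("g%d", 1:5))
  expect_equal(rank_agreement(p, p, "top_k", k = 3), 0)
  # swap of the top two
  q <- p; q[c("g1", "g2")] <- p[c("g2", "g1")]
  expect_equal(rank_agreement(p, q, "top_k", k = 3), 2 / 3)
  # full reversal within the top 3
  r <- p; r[c("g1", "g3")] <- p[c("g3", "g1")]
  expect_equal(rank_agreement(p, r, "top_k", k = 3), 4 / 3)
  # p-threshold selection on the truth ordering
  expect_equal(rank_agreement(p, q, "p_threshold", alpha = 0.01), 2 / 3)
  empty <- setNames(rep(0.9, 5), names(p))
  expect_warning(res <- rank_agreement(empty, q, "p_threshold", alpha = 0.05),
                 "empty")
  expect_true(is.na(res))
  expect_error(rank_agreement(p, q[1:3]), class = "taafgex_schema_error")
})

test_that("self-comparison in the subsample experiment is perfect and deterministic", {
  cfg <- generator_config(n_samples = 120, n_landmarks = 5, n_targets = 60,
                          noise_sd = 0.3, series_effect_sd = 0,
                          n_de_genes = 6, de_effect_size = 1.5, seed = 21)
  out <- generate_phenotype_dataset(cfg)
  truth <- target_matrix(out$dataset)
  res <- subsample_experiment(truth, list(self = truth),
                              out$dataset$phenotype, sizes = c(12, 20),
                              repetitions = 10, seed = 5)
  f1 <- res$results$value[res$results$metric == "f_1"]
  ranks <- res$results$value[grepl("rank", res$results$metric)]
  expect_true(all(f1 == 1))
  expect_true(all(ranks[is.finite(ranks)] == 0))
  res2 <- subsample_experiment(truth, list(self = truth),
                               out$dataset$phenotype, sizes = c(12, 20),
                               repetitions = 10, seed = 5)
  expect_identical(res$results, res2$results)
  # oversized requests are skipped with a warning
  expect_warning(
    subsample_experiment(truth, list(self = truth), out$dataset$phenotype,
                         sizes = c(1000, 12), repetitions = 2, seed = 1),
    "skipped")
})

test_that("lower inference noise yields better DE recovery at every size", {
  # the two phenotype classes emulate transcriptionally distinct clusters:
  # a sizable DE set with heterogeneous effects, so some genes sit near the
  # detection boundary at every study size
  cfg <- generator_config(n_samples = 400, n_landmarks = 5, n_targets = 100,
                          noise_sd = 0.3, series_effect_sd = 0,
                          n_de_genes = 30, de_effect_size = c(0.5, 4),
                          seed = 31)
  out <- generate_phenotype_dataset(cfg)
  truth <- target_matrix(out$dataset)
  withr::local_seed(32)
  inferred <- list(
    low = truth + matrix(rnorm(length(truth), sd = 0.1), nrow(truth)),
    high = truth + matrix(rnorm(length(truth), sd = 0.5), nrow(truth)))
  res <- subsample_experiment(truth, inferred, out$dataset$phenotype,
                              sizes = c(12, 60), repetitions = 50, seed = 7)
  med <- glance(res)
  for (s in c(12, 60)) {
    m_low <- med$median[med$method == "low" & med$size == s &
                          med$metric == "f_1"]
    m_high <- med$median[med$method == "high" & med$size == s &
                           med$metric == "f_1"]
    expect_gt(m_low, m_high)
  }
  p_f1 <- res$tests$wilcoxon_p[res$tests$metric == "f_1"]
  expect_true(all(p_f1 < 0.01))
})
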