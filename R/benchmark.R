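#' Paired TAAF-vs-fixed benchmark on synthetic data
#'
#' The desk-scale analogue of the headline architecture comparison: for each
#' seed, a synthetic landmark-to-target dataset is generated, globally
#' standardized and split 70/15/15; a TAAF network and a fixed-activation
#' network of identical architecture (same depth, width, inner activation,
#' dropout, weight-initialization seed) are trained with the same protocol;
#' and the pair is compared on test MMAE with the paired Wilcoxon test over
#' per-sample MAEs.  Negative MMDAE favors the TAAF network.
#'
#' @param seeds Integer vector; one paired run per seed (drives data
#'   generation, weight init and training).
#' @param generator A [generator_config()] template (its seed is replaced
#'   per run).
#' @param width,n_hidden_layers,inner_kind,dropout_rate Architecture
#'   settings shared by both networks.
#' @param output_mode Output head of the TAAF network (`"linear"` or
#'   `"taaf"`); the fixed network always uses the linear head.
#' @param n_epochs Training epochs per network.
#' @param fractions Train/validation/test split fractions.
#' @return A tibble with one row per seed: `seed`, `mmae_taaf`,
#'   `mmae_fixed`, `mmdae`, `wilcoxon_p`, `taaf_wins`.
#' @export
taaf_benchmark <- function(seeds = 1:10,
                           generator = generator_config(),
                           width = 32, n_hidden_layers = 1,
                           inner_kind = "sigmoid",
                           dropout_rate = 0.25,
                           output_mode = "linear",
                           n_epochs = 60,
                           fractions = c(0.7, 0.15, 0.15)) {
  rows <- lapply(seeds, function(s) {
    gen <- generator
    gen$seed <- as.integer(s)
    ds <- generate_expression(gen)$dataset
    std <- global_standardize(ds)$dataset
    splits <- random_split(std, fractions, seed = s)
    spec_taaf <- architecture_spec(
      input_dim = length(std$landmark_ids),
      output_dim = length(std$target_ids),
      n_hidden_layers = n_hidden_layers, width = width,
      dropout_rate = dropout_rate, inner_kind = inner_kind,
      hidden_mode = "taaf", output_mode = output_mode)
    spec_fixed <- spec_taaf
    spec_fixed$hidden_mode <- "fixed"
    spec_fixed$output_mode <- "linear"
    cfg <- training_config(n_epochs = n_epochs, seed = s)
    fit_taaf <- train_network(build_network(spec_taaf, seed = s),
                              splits$train, splits$validation, cfg)
    fit_fixed <- train_network(build_network(spec_fixed, seed = s),
                               splits$train, splits$validation, cfg)
    truth <- target_matrix(splits$test)
    pred_taaf <- predict(fit_taaf, splits$test)
    pred_fixed <- predict(fit_fixed, splits$test)
    mae_t <- mae_per_sample(truth, pred_taaf)
    mae_f <- mae_per_sample(truth, pred_fixed)
    tests <- paired_tests(mae_t, mae_f)
    tibble::tibble(
      seed = s, mmae_taaf = mmae(mae_t), mmae_fixed = mmae(mae_f),
      mmdae = mmae(mae_t) - mmae(mae_f),
      wilcoxon_p = tests[["wilcoxon_p"]],
      taaf_wins = mmae(mae_t) < mmae(mae_f))
  })
  dplyr::bind_rows(rows)
}
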