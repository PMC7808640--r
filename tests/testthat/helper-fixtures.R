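# shared fixture builders and independent oracles; everything is generated
# in code at test time

random_dataset <- function(n = 20, n_landmarks = 4, n_targets = 6, seed = 1,
                           series = NULL) {
  withr::local_seed(seed)
  values <- matrix(rnorm(n * (n_landmarks + n_targets)), n,
                   dimnames = list(
                     sprintf("S%03d", seq_len(n)),
                     c(sprintf("L%02d", seq_len(n_landmarks)),
                       sprintf("T%02d", seq_len(n_targets)))))
  expression_dataset(values, sprintf("L%02d", seq_len(n_landmarks)),
                     series = series)
}

# central finite difference of a scalar-argument function
fd <- function(f, h = 1e-5) (f(h) - f(-h)) / (2 * h)

# gradient-check error with the standard denominator floor
grad_relerr <- function(a, b) abs(a - b) / pmax(1, abs(a), abs(b))

# brute-force confusion-matrix scores, kept independent of confusion_scores()
brute_confusion <- function(truth, pred, beta = 1) {
  tab <- c(tp = sum(truth & pred), fp = sum(!truth & pred),
           fn = sum(truth & !pred), tn = sum(!truth & !pred))
  P <- tab["tp"] / (tab["tp"] + tab["fp"])
  R <- tab["tp"] / (tab["tp"] + tab["fn"])
  list(
    table = tab,
    accuracy = unname((tab["tp"] + tab["tn"]) / length(truth)),
    fbeta = unname((1 + beta^2) * P * R / (beta^2 * P + R)),
    mcc = unname((tab["tp"] * tab["tn"] - tab["fp"] * tab["fn"]) /
                   sqrt(prod(tab["tp"] + tab["fp"], tab["tp"] + tab["fn"],
                             tab["tn"] + tab["fp"], tab["tn"] + tab["fn"])))
  )
}

# count stored parameter values of a built network by direct enumeration
brute_param_count <- function(network, trainable_only = FALSE) {
  total <- 0L
  for (layer in network$layers) {
    total <- total + length(layer$W) + length(layer$bias)
    if (!is.null(layer$taaf)) {
      fields <- if (trainable_only) layer$taaf$mask else
        c("alpha", "beta", "gamma", "delta")
      for (f in fields) total <- total + length(layer$taaf[[f]])
    }
  }
  total
}

# tiny trained half-network fit on a random dataset (fast: 2 epochs)
tiny_fit <- function(dataset, target_ids, seed = 1, width = 3) {
  spec <- architecture_spec(length(dataset$landmark_ids), length(target_ids),
                            width = width, dropout_rate = 0,
                            hidden_mode = "taaf", output_mode = "linear")
  train_network(build_network(spec, seed), dataset, dataset,
                training_config(n_epochs = 2, batch_size = 8, seed = seed),
                target_ids = target_ids)
}
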