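#' Synthetic expression generator configuration
#'
#' Configures the seeded generator that emulates the structure of a large
#' microarray compendium used for landmark-based expression inference: a
#' low-dimensional latent state per sample, a landmark block that is a noisy
#' linear readout of the latents, and a target block of per-gene nonlinear
#' readouts with heterogeneous per-gene output scales and offsets (the range
#' mismatch that the TAAF's alpha/delta parameters can absorb).  Samples are
#' grouped into series with additive series-level intercepts, and a
#' two-class phenotype with a known set of differentially expressed target
#' genes can be planted.
#'
#' Defaults define the package's standard benchmark: 2,000 samples, 50
#' landmarks, 200 targets, 8 latent factors, observation noise sd 0.3,
#' per-gene scales in \[0.5, 3\] and offsets in \[-2, 2\], 20 series with
#' intercept sd 0.2, and 20 differentially expressed genes at effect size 2.
#'
#' @param n_samples,n_landmarks,n_targets,n_latent Positive integers.
#' @param nonlinearity Shape of the latent-to-target maps: `"tanh"`,
#'   `"sigmoid"`, or `"mixed"` (each target gene draws one of the two).
#' @param noise_sd Observation noise sd (applied to landmarks and targets).
#' @param target_scale_range Length-2 positive interval for per-gene output
#'   scales.
#' @param target_offset_range Length-2 interval for per-gene output offsets.
#' @param n_series Number of sample series (GEO-series-like groups).
#' @param series_effect_sd Sd of the additive per-series intercept.
#' @param n_de_genes Number of target genes shifted in phenotype class "B".
#' @param de_effect_size Size of that shift in expression units (before
#'   observation noise).  A scalar shifts every designated gene equally; a
#'   length-2 range draws one effect per gene uniformly from it, emulating
#'   the heterogeneous effect sizes of naturally distinct phenotype classes
#'   (some genes far above, some near the detection boundary).
#' @param seed Integer seed; all outputs are fully deterministic given the
#'   config.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(n_samples = 2000, n_landmarks = 50,
                             n_targets = 200, n_latent = 8,
                             nonlinearity = c("mixed", "tanh", "sigmoid"),
                             noise_sd = 0.3,
                             target_scale_range = c(0.5, 3),
                             target_offset_range = c(-2, 2),
                             n_series = 20, series_effect_sd = 0.2,
                             n_de_genes = 20, de_effect_size = 2,
                             seed = 1) {
  for (v in list(n_samples, n_landmarks, n_targets, n_latent, n_series)) {
    if (!is_count(v)) stop_argument("sizes must be positive integers")
  }
  if (noise_sd < 0 || series_effect_sd < 0) stop_argument("sds must be >= 0")
  if (missing(n_de_genes)) n_de_genes <- min(n_de_genes, n_targets)
  if (n_de_genes < 0 || n_de_genes > n_targets) {
    stop_argument("n_de_genes must lie in [0, n_targets]")
  }
  if (length(target_scale_range) != 2 || any(target_scale_range <= 0) ||
      diff(target_scale_range) < 0) {
    stop_argument("target_scale_range must be a positive interval")
  }
  if (!length(de_effect_size) %in% 1:2) {
    stop_argument("de_effect_size must be a scalar or a length-2 range")
  }
  structure(list(
    n_samples = as.integer(n_samples), n_landmarks = as.integer(n_landmarks),
    n_targets = as.integer(n_targets), n_latent = as.integer(n_latent),
    nonlinearity = match.arg(nonlinearity), noise_sd = noise_sd,
    target_scale_range = target_scale_range,
    target_offset_range = target_offset_range,
    n_series = as.integer(n_series), series_effect_sd = series_effect_sd,
    n_de_genes = as.integer(n_de_genes), de_effect_size = de_effect_size,
    seed = as.integer(seed)
  ), class = "generator_config")
}

# draw the generating maps and latent state; shared by both generators
draw_generating_model <- function(config) {
  k <- config$n_latent
  latents <- matrix(stats::rnorm(config$n_samples * k), config$n_samples, k)
  landmark_loadings <- matrix(stats::rnorm(k * config$n_landmarks), k,
                              config$n_landmarks) / sqrt(k)
  target_weights <- matrix(stats::rnorm(k * config$n_targets), k,
                           config$n_targets) / sqrt(k)
  scales <- stats::runif(config$n_targets, config$target_scale_range[1],
                         config$target_scale_range[2])
  offsets <- stats::runif(config$n_targets, config$target_offset_range[1],
                          config$target_offset_range[2])
  shapes <- switch(config$nonlinearity,
    tanh = rep("tanh", config$n_targets),
    sigmoid = rep("sigmoid", config$n_targets),
    mixed = sample(c("tanh", "sigmoid"), config$n_targets, replace = TRUE))
  series <- sort(rep_len(sprintf("GSE%03d", seq_len(config$n_series)),
                         config$n_samples))
  series_effects <- stats::setNames(
    stats::rnorm(config$n_series, 0, config$series_effect_sd),
    sprintf("GSE%03d", seq_len(config$n_series)))
  list(latents = latents, landmark_loadings = landmark_loadings,
       target_weights = target_weights, scales = scales, offsets = offsets,
       shapes = shapes, series = series, series_effects = series_effects)
}

# noiseless target block from a generating model (optionally with a per-gene
# additive shift for a subset of samples — the planted DE effect, applied on
# the gene's output scale so the effect size is in expression units)
eval_target_maps <- function(model, de_shift = NULL) {
  lin <- model$latents %*% model$target_weights
  shaped <- lin
  tanh_cols <- model$shapes == "tanh"
  shaped[, tanh_cols] <- tanh(lin[, tanh_cols, drop = FALSE])
  shaped[, !tanh_cols] <- stats::plogis(lin[, !tanh_cols, drop = FALSE])
  out <- sweep(sweep(shaped, 2, model$scales, "*"), 2, model$offsets, "+")
  if (!is.null(de_shift)) out <- out + de_shift
  out
}

#' Generate a synthetic landmark-to-target expression dataset
#'
#' Latent factors are standard normal per sample; landmarks are a linear map
#' of the latents plus noise; each target gene is a scaled and shifted
#' nonlinear (tanh or sigmoid) map of the latents plus noise; series labels
#' add a per-series random intercept to every gene.  The returned ground
#' truth retains every generating map, so the noiseless expression is
#' recomputable exactly.
#'
#' @param config A [generator_config()].
#' @return A list with elements `dataset` (an [expression_dataset()]) and
#'   `truth` (generating maps, noiseless landmark/target matrices, series
#'   effects).
#' @export
generate_expression <- function(config) {
  if (!inherits(config, "generator_config")) {
    stop_argument("config must be a generator_config")
  }
  with_seed(config$seed, {
    model <- draw_generating_model(config)
    build_synthetic_dataset(config, model, de_shift = NULL,
                            phenotype = NULL)
  })
}

build_synthetic_dataset <- function(config, model, de_shift, phenotype,
                                    de_flags = NULL) {
  noiseless_landmarks <- model$latents %*% model$landmark_loadings
  noiseless_targets <- eval_target_maps(model, de_shift)
  n <- config$n_samples
  landmarks <- noiseless_landmarks +
    config$noise_sd * matrix(stats::rnorm(n * config$n_landmarks), n)
  targets <- noiseless_targets +
    config$noise_sd * matrix(stats::rnorm(n * config$n_targets), n)
  s_eff <- model$series_effects[model$series]
  landmarks <- landmarks + s_eff
  targets <- targets + s_eff
  landmark_ids <- sprintf("L%03d", seq_len(config$n_landmarks))
  target_ids <- sprintf("T%04d", seq_len(config$n_targets))
  samples <- sprintf("S%05d", seq_len(n))
  values <- cbind(landmarks, targets)
  dimnames(values) <- list(samples, c(landmark_ids, target_ids))
  colnames(noiseless_landmarks) <- landmark_ids
  colnames(noiseless_targets) <- target_ids
  rownames(noiseless_landmarks) <- rownames(noiseless_targets) <- samples
  dataset <- expression_dataset(values, landmark_ids,
                                series = model$series,
                                phenotype = phenotype)
  truth <- list(model = model,
                noiseless_landmarks = noiseless_landmarks,
                noiseless_targets = noiseless_targets,
                de_flags = de_flags)
  list(dataset = dataset, truth = truth)
}

#' Generate a two-class phenotype dataset with planted DE genes
#'
#' As [generate_expression()], but samples are split into two phenotype
#' classes "A" and "B"; in class "B" exactly `n_de_genes` designated target
#' genes are shifted by `de_effect_size` on the latent-to-target map (before
#' observation noise).  The returned DE flags mark exactly those genes.
#'
#' @param config A [generator_config()] with `n_de_genes >= 1` for a
#'   meaningful fixture (`0` gives the null dataset: no truly differential
#'   genes, all flags `FALSE`).
#' @return A list with elements `dataset` (phenotype labels attached) and
#'   `truth` (including `de_flags`, a named logical over target genes, and
#'   the noiseless matrices used as DE ground truth).
#' @export
generate_phenotype_dataset <- function(config) {
  if (!inherits(config, "generator_config")) {
    stop_argument("config must be a generator_config")
  }
  with_seed(config$seed, {
    model <- draw_generating_model(config)
    n <- config$n_samples
    phenotype <- rep(c("A", "B"), length.out = n)
    de_idx <- if (config$n_de_genes > 0) {
      sample.int(config$n_targets, config$n_de_genes)
    } else integer(0)
    de_flags <- stats::setNames(rep(FALSE, config$n_targets),
                                sprintf("T%04d", seq_len(config$n_targets)))
    de_flags[de_idx] <- TRUE
    eff <- config$de_effect_size
    effects <- if (length(eff) == 2) {
      stats::runif(length(de_idx), eff[1], eff[2])
    } else {
      rep(eff, length(de_idx))
    }
    de_shift <- matrix(0, n, config$n_targets)
    if (length(de_idx) && any(effects != 0)) {
      de_shift[phenotype == "B", de_idx] <-
        rep(effects, each = sum(phenotype == "B"))
    } else {
      de_flags[] <- FALSE  # zero effect size: nothing is truly differential
    }
    build_synthetic_dataset(config, model, de_shift = de_shift,
                            phenotype = phenotype, de_flags = de_flags)
  })
}

#' Write generator ground truth as a tab-delimited sidecar
#'
#' One row per target gene: id, DE flag, generating scale and offset.
#'
#' @param truth The `truth` element returned by the generators.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  ids <- colnames(truth$noiseless_targets)
  df <- data.frame(
    gene_id = ids,
    is_de = if (!is.null(truth$de_flags)) truth$de_flags[ids] else FALSE,
    scale = truth$model$scales,
    offset = truth$model$offsets
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
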