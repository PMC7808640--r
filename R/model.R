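#' D-GEX-style architecture specification
#'
#' Describes one member of the feed-forward architecture family used for
#' landmark-to-target expression inference: 1-3 fully connected hidden
#' layers of equal width, dropout on hidden activations (default rate 0.25),
#' and a linear or TAAF output layer with one unit per target gene.  Hidden
#' units either use the fixed inner activation (`hidden_mode = "fixed"`,
#' with a conventional bias) or wrap it in a TAAF
#' (`hidden_mode = "taaf"`, in which case gamma plays the role of the bias
#' and no separate bias is kept).
#'
#' @param input_dim Number of landmark genes feeding the network.
#' @param output_dim Number of target genes served by this network.
#' @param n_hidden_layers 1, 2 or 3.
#' @param width Units per hidden layer (equal across layers).
#' @param dropout_rate Dropout rate on hidden activations, in `[0, 1)`.
#' @param inner_kind Inner activation of hidden (and TAAF output) units:
#'   `"tanh"` or `"sigmoid"`.
#' @param hidden_mode `"fixed"` or `"taaf"`.
#' @param output_mode `"linear"` (the classical regression head) or
#'   `"taaf"` (the TAAFo variant: the output units' alpha/delta provide the
#'   arbitrary output range a linear head otherwise supplies).
#' @param adaptivity_mask Trainable subset of the TAAF parameters, used by
#'   any TAAF layer in the network.
#' @return An object of class `architecture_spec`.
#' @export
architecture_spec <- function(input_dim, output_dim,
                              n_hidden_layers = 1, width = 3000,
                              dropout_rate = 0.25,
                              inner_kind = c("tanh", "sigmoid"),
                              hidden_mode = c("fixed", "taaf"),
                              output_mode = c("linear", "taaf"),
                              adaptivity_mask = TAAF_PARAM_NAMES) {
  if (!is_count(input_dim) || !is_count(output_dim)) {
    stop_argument("input_dim and output_dim must be positive integers")
  }
  if (!is_count(n_hidden_layers) || !n_hidden_layers %in% 1:3) {
    stop_argument("n_hidden_layers must be 1, 2 or 3")
  }
  if (!is_count(width)) stop_argument("width must be a positive integer")
  if (!is.numeric(dropout_rate) || length(dropout_rate) != 1 ||
      dropout_rate < 0 || dropout_rate >= 1) {
    stop_argument("dropout_rate must lie in [0, 1)")
  }
  structure(list(
    input_dim = as.integer(input_dim), output_dim = as.integer(output_dim),
    n_hidden_layers = as.integer(n_hidden_layers), width = as.integer(width),
    dropout_rate = dropout_rate,
    inner_kind = match.arg(inner_kind),
    hidden_mode = match.arg(hidden_mode),
    output_mode = match.arg(output_mode),
    adaptivity_mask = validate_mask(adaptivity_mask)
  ), class = "architecture_spec")
}

#' @export
print.architecture_spec <- function(x, ...) {
  cat(sprintf(
    "<architecture_spec: %d -> %s -> %d | hidden: %s(%s) | output: %s | dropout %.2f | mask {%s}>\n",
    x$input_dim, paste(rep(x$width, x$n_hidden_layers), collapse = " -> "),
    x$output_dim, x$hidden_mode, x$inner_kind, x$output_mode, x$dropout_rate,
    paste(x$adaptivity_mask, collapse = ",")))
  invisible(x)
}

spec_layer_dims <- function(spec) {
  c(spec$input_dim, rep(spec$width, spec$n_hidden_layers), spec$output_dim)
}

#' Build a network from an architecture specification
#'
#' Weights are drawn by normalized (Glorot) initialization: uniform on
#' `[-sqrt(6/(fan_in + fan_out)), +sqrt(6/(fan_in + fan_out))]`.  Biases
#' start at zero and TAAF parameters at `(1, 1, 0, 0)`, so a TAAF network
#' and its fixed-activation twin start from identical functions.  Fully
#' deterministic given `(spec, seed)`.
#'
#' @param spec An [architecture_spec()].
#' @param seed Integer seed for the weight draw.
#' @return An object of class `dgex_network`: the spec plus a list of layer
#'   parameter sets.
#' @export
build_network <- function(spec, seed) {
  if (!inherits(spec, "architecture_spec")) {
    stop_argument("spec must be an architecture_spec")
  }
  dims <- spec_layer_dims(spec)
  n_layers <- length(dims) - 1L
  layers <- with_seed(seed, {
    lapply(seq_len(n_layers), function(k) {
      fan_in <- dims[k]; fan_out <- dims[k + 1]
      lim <- sqrt(6 / (fan_in + fan_out))
      W <- matrix(stats::runif(fan_in * fan_out, -lim, lim), fan_in, fan_out)
      is_output <- k == n_layers
      mode <- if (is_output) {
        if (spec$output_mode == "linear") "linear" else "taaf"
      } else spec$hidden_mode
      layer <- list(W = W, is_output = is_output, mode = mode)
      if (mode == "taaf") {
        layer$taaf <- init_taaf(fan_out, spec$adaptivity_mask)
        layer$inner <- spec$inner_kind
      } else if (mode == "fixed") {
        layer$bias <- numeric(fan_out)
        layer$inner <- spec$inner_kind
      } else {  # linear output head
        layer$bias <- numeric(fan_out)
        layer$inner <- "identity"
      }
      layer
    })
  })
  structure(list(spec = spec, layers = layers, seed = as.integer(seed),
                 format_version = 1L),
            class = "dgex_network")
}

#' @export
print.dgex_network <- function(x, ...) {
  cat("<dgex_network>\n  ")
  print(x$spec)
  cat(sprintf("  parameters: %d (seed %d)\n",
              parameter_count(x$spec), x$seed))
  invisible(x)
}

# forward pass; when cache = TRUE returns per-layer intermediates for
# backpropagation.  Dropout masks (inverted scaling) are drawn from the
# *current* RNG stream — callers own seeding.
forward_pass <- function(network, X, training = FALSE, cache = FALSE) {
  if (!is.matrix(X)) X <- matrix(X, nrow = 1)
  if (ncol(X) != network$spec$input_dim) {
    stop_dimension(sprintf("input has %d columns; network expects %d",
                           ncol(X), network$spec$input_dim))
  }
  p <- network$spec$dropout_rate
  caches <- if (cache) vector("list", length(network$layers))
  A <- X
  for (k in seq_along(network$layers)) {
    layer <- network$layers[[k]]
    Z <- A %*% layer$W
    if (!is.null(layer$bias)) Z <- sweep(Z, 2, layer$bias, "+")
    if (layer$mode == "taaf") {
      parts <- taaf_partials(Z, layer$taaf, layer$inner)
      act <- parts$value
    } else {
      inner <- as_inner(layer$inner)
      act <- inner$value(Z)
      parts <- NULL
    }
    mask <- NULL
    if (training && !layer$is_output && p > 0) {
      keep <- 1 - p
      mask <- matrix(stats::rbinom(length(act), 1, keep) / keep,
                     nrow(act), ncol(act))
      out <- act * mask
    } else {
      out <- act
    }
    if (cache) {
      caches[[k]] <- list(X_in = A, Z = Z, parts = parts, mask = mask)
    }
    A <- out
  }
  if (cache) list(output = A, caches = caches) else A
}

#' Run a network forward
#'
#' Applies the network to a matrix of landmark expression (samples in rows).
#' At evaluation time (`training = FALSE`) the pass is deterministic and
#' dropout is a no-op.  At training time, inverted dropout is applied to
#' hidden activations — activations are scaled by `1/(1-rate)` at train time
#' so that evaluation needs no rescaling.
#'
#' @param network A [build_network()] result.
#' @param landmarks Samples-by-input_dim numeric matrix.
#' @param training Apply dropout?
#' @param seed Optional seed for the dropout draw (only used when
#'   `training = TRUE`).
#' @return Samples-by-output_dim matrix of predictions.
#' @export
forward <- function(network, landmarks, training = FALSE, seed = NULL) {
  if (training && !is.null(seed)) {
    with_seed(seed, forward_pass(network, landmarks, training = TRUE))
  } else {
    forward_pass(network, landmarks, training = training)
  }
}

#' Count network parameters
#'
#' Counting conventions: a fixed-activation unit owns its incoming weights
#' plus one bias; a TAAF unit owns its incoming weights plus its four TAAF
#' parameters and no bias (gamma doubles as the bias); a linear output unit
#' owns weights plus one bias.  With `trainable_only = TRUE`, TAAF
#' parameters outside the adaptivity mask are excluded.
#'
#' @param spec An [architecture_spec()].
#' @param trainable_only Exclude frozen TAAF parameters?
#' @return Integer count.
#' @export
parameter_count <- function(spec, trainable_only = FALSE) {
  dims <- spec_layer_dims(spec)
  n_layers <- length(dims) - 1L
  taaf_per_unit <- if (trainable_only) length(spec$adaptivity_mask) else 4L
  total <- 0L
  for (k in seq_len(n_layers)) {
    fan_in <- dims[k]; fan_out <- dims[k + 1]
    is_output <- k == n_layers
    mode <- if (is_output) {
      if (spec$output_mode == "linear") "linear" else "taaf"
    } else spec$hidden_mode
    per_unit <- fan_in + if (mode == "taaf") taaf_per_unit else 1L
    total <- total + fan_out * per_unit
  }
  as.integer(total)
}

#' Capacity-matched width for a TAAF network
#'
#' Given a fixed-activation reference architecture and a TAAF template of
#' the same depth and input/output dimensions, returns the largest hidden
#' width `W` such that the template at width `W` has at most as many
#' parameters as the reference, while width `W + 1` would exceed it.  This
#' is how a TAAF network is shrunk so that an observed improvement cannot be
#' attributed to its extra per-unit parameters.
#'
#' @param reference An [architecture_spec()] with `hidden_mode = "fixed"`.
#' @param template An [architecture_spec()] template (typically
#'   `hidden_mode = "taaf"`); its `width` field is ignored.
#' @param trainable_only Counting convention passed to [parameter_count()].
#' @return The matched width (positive integer).
#' @export
capacity_matched_width <- function(reference, template, trainable_only = FALSE) {
  if (reference$n_hidden_layers != template$n_hidden_layers ||
      reference$input_dim != template$input_dim ||
      reference$output_dim != template$output_dim) {
    stop_argument("reference and template must share depth, input_dim and output_dim")
  }
  budget <- parameter_count(reference, trainable_only = trainable_only)
  count_at <- function(w) {
    t2 <- template; t2$width <- as.integer(w)
    parameter_count(t2, trainable_only = trainable_only)
  }
  if (count_at(1) > budget) {
    stop_infeasible("no width >= 1 fits within the reference parameter budget")
  }
  # parameter count is strictly increasing in width; exponential + binary search
  hi <- 1L
  while (count_at(hi * 2L) <= budget) hi <- hi * 2L
  lo <- hi; hi <- hi * 2L
  while (hi - lo > 1L) {
    mid <- (lo + hi) %/% 2L
    if (count_at(mid) <= budget) lo <- mid else hi <- mid
  }
  lo
}

#' Randomly split target genes into two halves
#'
#' The target-gene set is split into two disjoint halves whose sizes differ
#' by at most one, so that each half can be served by its own network (the
#' two half-networks of the D-GEX design).  Ids are sorted before the seeded
#' shuffle, so the split is a function of the id set, not of input order.
#'
#' @param gene_ids Character vector of at least 2 unique gene ids.
#' @param seed Integer seed.
#' @return A list with elements `half1` and `half2` (sorted id vectors).
#' @export
split_target_genes <- function(gene_ids, seed) {
  gene_ids <- as.character(gene_ids)
  if (length(gene_ids) < 2) stop_argument("need at least 2 gene ids to split")
  if (anyDuplicated(gene_ids)) stop_argument("gene ids must be unique")
  ids <- sort(gene_ids)
  n <- length(ids)
  perm <- with_seed(seed, sample.int(n))
  n1 <- ceiling(n / 2)
  list(half1 = sort(ids[perm[seq_len(n1)]]),
       half2 = sort(ids[perm[(n1 + 1):n]]))
}

#' Serialize a network to a versioned JSON checkpoint
#'
#' The checkpoint holds the architecture spec, every weight matrix, bias
#' vector and TAAF parameter vector, and the build seed, under documented
#' keys (`spec/*`, `layer_k/weights`, `layer_k/bias`,
#' `layer_k/taaf/{alpha,beta,gamma,delta}`, `meta/seed`,
#' `meta/format_version`).  Values are written at full double precision.
#'
#' @param network A `dgex_network`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_checkpoint <- function(network, path) {
  layers <- lapply(network$layers, function(layer) {
    # dims stored explicitly: JSON has no matrix type and degenerate shapes
    # (1 x n) must survive the round trip
    out <- list(weights = list(dim = dim(layer$W), data = as.vector(layer$W)),
                mode = layer$mode, inner = layer$inner)
    if (!is.null(layer$bias)) out$bias <- layer$bias
    if (!is.null(layer$taaf)) {
      out$taaf <- list(alpha = layer$taaf$alpha, beta = layer$taaf$beta,
                       gamma = layer$taaf$gamma, delta = layer$taaf$delta,
                       mask = layer$taaf$mask)
    }
    out
  })
  names(layers) <- paste0("layer_", seq_along(layers))
  payload <- c(
    list(spec = unclass(network$spec)),
    layers,
    list(meta = list(seed = network$seed, format_version = network$format_version))
  )
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' Read a network checkpoint
#'
#' @param path Path written by [write_checkpoint()].
#' @return A `dgex_network`.
#' @export
read_checkpoint <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  sp <- payload$spec
  spec <- architecture_spec(
    input_dim = sp$input_dim, output_dim = sp$output_dim,
    n_hidden_layers = sp$n_hidden_layers, width = sp$width,
    dropout_rate = sp$dropout_rate, inner_kind = sp$inner_kind,
    hidden_mode = sp$hidden_mode, output_mode = sp$output_mode,
    adaptivity_mask = sp$adaptivity_mask %||% character(0))
  layer_keys <- grep("^layer_", names(payload), value = TRUE)
  layer_keys <- layer_keys[order(as.integer(sub("layer_", "", layer_keys)))]
  n_layers <- length(layer_keys)
  layers <- lapply(seq_along(layer_keys), function(k) {
    raw <- payload[[layer_keys[k]]]
    W <- matrix(as.numeric(raw$weights$data),
                raw$weights$dim[1], raw$weights$dim[2])
    layer <- list(W = W, is_output = k == n_layers,
                  mode = raw$mode, inner = raw$inner)
    if (!is.null(raw$bias)) layer$bias <- as.numeric(raw$bias)
    if (!is.null(raw$taaf)) {
      layer$taaf <- taaf_parameters(raw$taaf$alpha, raw$taaf$beta,
                                    raw$taaf$gamma, raw$taaf$delta,
                                    raw$taaf$mask %||% character(0))
    }
    layer
  })
  structure(list(spec = spec, layers = layers,
                 seed = as.integer(payload$meta$seed),
                 format_version = as.integer(payload$meta$format_version)),
            class = "dgex_network")
}
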