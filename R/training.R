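#' Training configuration
#'
#' Hyperparameters of the training protocol: mini-batch optimization with
#' the Nadam optimizer (Adam with Nesterov momentum) at learning rate
#' 0.0005, beta1 = 0.9, beta2 = 0.999 and momentum schedule decay 0.004,
#' batch size 256, and best-epoch model selection on validation MMAE.  The
#' full-scale protocol runs 600 epochs; `n_epochs` is configurable down for
#' desk-scale work.  The training loss defaults to squared error while all
#' reported metrics are MAE-based; `loss_kind = "absolute-error"` switches
#' the loss itself to MAE.
#'
#' @param learning_rate Positive step size.
#' @param beta1,beta2 Nadam moment decay rates, in (0, 1).
#' @param schedule_decay Nesterov momentum schedule decay `eta`: the
#'   momentum schedule is `psi(t) = beta1 * (1 - 0.5 * 0.96^(t * eta))`
#'   per update step.
#' @param batch_size Mini-batch size (>= 1).
#' @param n_epochs Number of epochs (>= 1).
#' @param loss_kind `"squared-error"` or `"absolute-error"`.
#' @param seed Seed for epoch shuffling and dropout.
#' @return An object of class `training_config`.
#' @export
training_config <- function(learning_rate = 0.0005, beta1 = 0.9,
                            beta2 = 0.999, schedule_decay = 0.004,
                            batch_size = 256, n_epochs = 600,
                            loss_kind = c("squared-error", "absolute-error"),
                            seed = 1) {
  if (learning_rate <= 0) stop_argument("learning_rate must be > 0")
  if (beta1 <= 0 || beta1 >= 1 || beta2 <= 0 || beta2 >= 1) {
    stop_argument("beta1 and beta2 must lie in (0, 1)")
  }
  if (!is_count(batch_size)) stop_argument("batch_size must be >= 1")
  if (!is_count(n_epochs)) stop_argument("n_epochs must be >= 1")
  structure(list(
    learning_rate = learning_rate, beta1 = beta1, beta2 = beta2,
    schedule_decay = schedule_decay, batch_size = as.integer(batch_size),
    n_epochs = as.integer(n_epochs), loss_kind = match.arg(loss_kind),
    seed = as.integer(seed)
  ), class = "training_config")
}

# ---------------------------------------------------------------------------
# Nadam optimizer (Dozat's Nesterov-momentum Adam, keras conventions).
# State: first/second moment per parameter array plus the running momentum
# schedule product; `t` counts update steps from 1.

nadam_state <- function() {
  list(t = 0L, m_schedule = 1, m = list(), v = list())
}

nadam_mu <- function(t, beta1, eta) beta1 * (1 - 0.5 * 0.96^(t * eta))

# one Nadam step over a flat named list of gradient arrays; params and state
# are updated and returned
nadam_step <- function(params, grads, state, config, eps = 1e-8) {
  t <- state$t + 1L
  mu_t <- nadam_mu(t, config$beta1, config$schedule_decay)
  mu_tp1 <- nadam_mu(t + 1L, config$beta1, config$schedule_decay)
  m_sched <- state$m_schedule * mu_t
  m_sched_next <- m_sched * mu_tp1
  for (key in names(grads)) {
    g <- grads[[key]]
    if (is.null(g)) next
    m_prev <- state$m[[key]] %||% (g * 0)
    v_prev <- state$v[[key]] %||% (g * 0)
    m <- config$beta1 * m_prev + (1 - config$beta1) * g
    v <- config$beta2 * v_prev + (1 - config$beta2) * g^2
    g_hat <- g / (1 - m_sched)
    m_hat <- m / (1 - m_sched_next)
    v_hat <- v / (1 - config$beta2^t)
    m_bar <- (1 - mu_t) * g_hat + mu_tp1 * m_hat
    params[[key]] <- params[[key]] - config$learning_rate * m_bar / (sqrt(v_hat) + eps)
    state$m[[key]] <- m
    state$v[[key]] <- v
  }
  state$t <- t
  state$m_schedule <- m_sched
  list(params = params, state = state)
}

# ---------------------------------------------------------------------------
# backpropagation through a dgex_network

loss_value <- function(pred, truth, kind) {
  if (kind == "squared-error") mean((pred - truth)^2) else mean(abs(pred - truth))
}

loss_grad <- function(pred, truth, kind) {
  n <- length(pred)
  if (kind == "squared-error") 2 * (pred - truth) / n else sign(pred - truth) / n
}

# flat parameter list keyed "k.field" for the optimizer
network_param_list <- function(network) {
  out <- list()
  for (k in seq_along(network$layers)) {
    layer <- network$layers[[k]]
    out[[paste0(k, ".W")]] <- layer$W
    if (!is.null(layer$bias)) out[[paste0(k, ".bias")]] <- layer$bias
    if (!is.null(layer$taaf)) {
      for (p in layer$taaf$mask) out[[paste0(k, ".", p)]] <- layer$taaf[[p]]
    }
  }
  out
}

set_network_params <- function(network, params) {
  for (key in names(params)) {
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    k <- as.integer(parts[1]); field <- parts[2]
    if (field %in% c("W", "bias")) {
      network$layers[[k]][[field]] <- params[[key]]
    } else {
      network$layers[[k]]$taaf[[field]] <- params[[key]]
    }
  }
  network
}

# gradients of the loss wrt every *trainable* parameter; frozen TAAF
# parameters (outside the adaptivity mask) get no entry and are never touched
backward_pass <- function(network, fwd, X, Y, loss_kind) {
  grads <- list()
  dA <- loss_grad(fwd$output, Y, loss_kind)
  for (k in rev(seq_along(network$layers))) {
    layer <- network$layers[[k]]
    cache <- fwd$caches[[k]]
    if (!is.null(cache$mask)) dA <- dA * cache$mask
    if (layer$mode == "taaf") {
      parts <- cache$parts
      dZ <- dA * parts$d_y
      for (p in layer$taaf$mask) {
        grads[[paste0(k, ".", p)]] <-
          colSums(dA * parts[[paste0("d_", p)]])
      }
    } else if (layer$mode == "fixed") {
      inner <- as_inner(layer$inner)
      dZ <- dA * inner$derivative(cache$Z)
      grads[[paste0(k, ".bias")]] <- colSums(dZ)
    } else {  # linear head
      dZ <- dA
      grads[[paste0(k, ".bias")]] <- colSums(dZ)
    }
    grads[[paste0(k, ".W")]] <- crossprod(cache$X_in, dZ)
    if (k > 1) dA <- tcrossprod(dZ, layer$W)
  }
  grads
}

align_training_matrices <- function(network, dataset, target_ids) {
  X <- landmark_matrix(dataset)
  if (ncol(X) != network$spec$input_dim) {
    stop_schema(sprintf("dataset has %d landmarks; network expects %d",
                        ncol(X), network$spec$input_dim))
  }
  if (!all(target_ids %in% dataset$target_ids)) {
    stop_schema("network target ids missing from dataset")
  }
  list(X = X, Y = target_matrix(dataset, target_ids))
}

#' Train a network with the Nadam protocol
#'
#' Runs `n_epochs` of mini-batch Nadam updates on standardized expression
#' data, shuffling sample order each epoch under the config seed, and
#' evaluates validation MMAE after every epoch.  Parameters are snapshot
#' whenever validation MMAE improves; the returned model is the best epoch's
#' snapshot (first occurrence on ties), not the last.  TAAF parameters
#' outside the adaptivity mask are never updated.  Fully deterministic given
#' the network, data and config.
#'
#' @param network A [build_network()] result.
#' @param train_data,val_data [expression_dataset()]s, column-aligned with
#'   the network (standardize first; see [global_standardize()]).
#' @param config A [training_config()].
#' @param target_ids Target gene ids served by this network, in output
#'   column order.  Default: all target genes of `train_data` (requires
#'   `output_dim` to match).
#' @return An object of class `dgex_fit`: list with elements `network`
#'   (best snapshot), `history` (tibble: epoch, train_loss, val_mmae),
#'   `best_epoch` (1-based), `landmark_ids`, `target_ids`, `config`.
#' @export
train_network <- function(network, train_data, val_data, config,
                          target_ids = NULL) {
  target_ids <- target_ids %||% train_data$target_ids
  if (length(target_ids) != network$spec$output_dim) {
    stop_schema(sprintf("%d target ids given; network serves %d outputs",
                        length(target_ids), network$spec$output_dim))
  }
  tr <- align_training_matrices(network, train_data, target_ids)
  va <- align_training_matrices(network, val_data, target_ids)
  n <- nrow(tr$X)
  params <- network_param_list(network)
  state <- nadam_state()
  best_val <- Inf
  best_params <- params
  best_epoch <- NA_integer_
  train_loss <- val_mmae <- numeric(config$n_epochs)
  with_seed(config$seed, {
    for (epoch in seq_len(config$n_epochs)) {
      idx <- sample.int(n)
      starts <- seq(1, n, by = config$batch_size)
      batch_losses <- numeric(length(starts))
      for (b in seq_along(starts)) {
        rows <- idx[starts[b]:min(starts[b] + config$batch_size - 1L, n)]
        Xb <- tr$X[rows, , drop = FALSE]
        Yb <- tr$Y[rows, , drop = FALSE]
        net_cur <- set_network_params(network, params)
        fwd <- forward_pass(net_cur, Xb, training = TRUE, cache = TRUE)
        l <- loss_value(fwd$output, Yb, config$loss_kind)
        if (!is.finite(l)) {
          stop_divergence(sprintf("non-finite training loss at epoch %d", epoch))
        }
        batch_losses[b] <- l
        grads <- backward_pass(net_cur, fwd, Xb, Yb, config$loss_kind)
        upd <- nadam_step(params, grads, state, config)
        params <- upd$params
        state <- upd$state
      }
      train_loss[epoch] <- mean(batch_losses)
      net_cur <- set_network_params(network, params)
      pred <- forward_pass(net_cur, va$X, training = FALSE)
      val_mmae[epoch] <- mmae(mae_per_sample(va$Y, pred))
      if (val_mmae[epoch] < best_val) {
        best_val <- val_mmae[epoch]
        best_params <- params
        best_epoch <- epoch
      }
    }
  })
  structure(list(
    network = set_network_params(network, best_params),
    history = tibble::tibble(epoch = seq_len(config$n_epochs),
                             train_loss = train_loss, val_mmae = val_mmae),
    best_epoch = best_epoch,
    landmark_ids = colnames(tr$X),
    target_ids = target_ids,
    config = config
  ), class = "dgex_fit")
}

#' @export
print.dgex_fit <- function(x, ...) {
  cat(sprintf(
    "<dgex_fit: %d epochs, best epoch %d (val MMAE %.5f), %d -> %d genes>\n",
    nrow(x$history), x$best_epoch, min(x$history$val_mmae),
    length(x$landmark_ids), length(x$target_ids)))
  invisible(x)
}

#' Predict target expression from a fitted network
#'
#' @param object A [train_network()] fit.
#' @param newdata An [expression_dataset()] or a samples-by-landmarks
#'   matrix (columns ordered as at training time).
#' @param ... Unused.
#' @return Samples-by-targets matrix with gene ids as column names.
#' @export
predict.dgex_fit <- function(object, newdata, ...) {
  X <- if (inherits(newdata, "expression_dataset")) {
    landmark_matrix(newdata, object$landmark_ids)
  } else newdata
  pred <- forward_pass(object$network, X, training = FALSE)
  dimnames(pred) <- list(rownames(X), object$target_ids)
  pred
}

#' Compose predictions from two half-networks
#'
#' The two fitted half-networks must serve disjoint target-gene sets whose
#' union is the full target set; their predictions are concatenated and
#' ordered by the canonical gene-id order.
#'
#' @param fits List of two [train_network()] fits (more are accepted as long
#'   as their target sets partition the whole).
#' @param landmarks An [expression_dataset()] or landmark matrix.
#' @param gene_order Canonical target-gene order of the output; default is
#'   the sorted union of the fits' target ids.
#' @return Samples-by-all-targets matrix.
#' @export
predict_full_profile <- function(fits, landmarks, gene_order = NULL) {
  if (inherits(fits, "dgex_fit")) fits <- list(fits)
  all_ids <- unlist(lapply(fits, `[[`, "target_ids"))
  if (anyDuplicated(all_ids)) {
    stop_schema("half-networks overlap: some target genes served twice")
  }
  gene_order <- gene_order %||% sort(all_ids)
  if (!setequal(all_ids, gene_order)) {
    stop_schema("half-networks do not cover the full target set")
  }
  preds <- lapply(fits, predict, newdata = landmarks)
  out <- do.call(cbind, preds)
  out[, gene_order, drop = FALSE]
}

#' Fit a single TAAF unit to scalar data
#'
#' Fits the four parameters of one TAAF unit `g(y) = alpha * f(beta*y +
#' gamma) + delta` (input weight fixed at 1) to observed `(y, target)`
#' pairs by full-batch Nadam on the squared error, starting from the
#' canonical initialization `(1, 1, 0, 0)` and using the analytic partials.
#' Because `f` is odd for the tanh inner function, the parameterization is
#' only identified up to the sign orbit `(alpha, beta, gamma, delta) ~
#' (-alpha, -beta, -gamma, delta)`.
#'
#' @param y Numeric vector of inputs.
#' @param target Numeric vector of observed outputs.
#' @param inner Inner activation kind.
#' @param mask Trainable subset of the parameters.
#' @param learning_rate Nadam step size (full batch, so larger than the
#'   mini-batch default).
#' @param n_iter Number of full-batch updates.
#' @param config Optional [training_config()] overriding the optimizer
#'   moments.
#' @return A list with `params` (named numeric of length 4), `loss`
#'   (final mean squared error) and `trace` (loss every 100 iterations).
#' @export
fit_taaf_unit <- function(y, target, inner = "tanh",
                          mask = TAAF_PARAM_NAMES,
                          learning_rate = 0.02, n_iter = 5000,
                          config = NULL) {
  if (length(y) != length(target)) stop_dimension("y and target lengths differ")
  config <- config %||% training_config(learning_rate = learning_rate,
                                        n_epochs = 1)
  config$learning_rate <- learning_rate
  mask <- validate_mask(mask)
  params <- list(alpha = 1, beta = 1, gamma = 0, delta = 0)
  state <- nadam_state()
  trace <- numeric(0)
  for (it in seq_len(n_iter)) {
    tp <- taaf_parameters(params$alpha, params$beta, params$gamma,
                          params$delta, mask)
    parts <- taaf_partials(y, tp, inner)
    resid <- parts$value - target
    l <- mean(resid^2)
    if (!is.finite(l)) stop_divergence(sprintf("non-finite loss at iteration %d", it))
    if (it %% 100 == 1) trace <- c(trace, l)
    dL <- 2 * resid / length(y)
    grads <- list()
    for (p in mask) grads[[p]] <- sum(dL * parts[[paste0("d_", p)]])
    upd <- nadam_step(params, grads, state, config)
    params <- upd$params
    state <- upd$state
  }
  tp <- taaf_parameters(params$alpha, params$beta, params$gamma,
                        params$delta, mask)
  final <- mean((taaf_value(y, tp, inner) - target)^2)
  list(params = unlist(params[TAAF_PARAM_NAMES]), loss = final, trace = trace)
}

#' Write a training history as tab-delimited text
#'
#' @param fit A [train_network()] fit.
#' @param path Output file (columns: epoch, train_loss, val_mmae).
#' @return `path`, invisibly.
#' @export
write_history <- function(fit, path) {
  utils::write.table(fit$history, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
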