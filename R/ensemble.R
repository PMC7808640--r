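#' Per-gene mean absolute error
#'
#' For each gene (column), the mean over samples of the absolute prediction
#' error — the selection statistic for per-gene expert assignment.
#'
#' @param truth,prediction Samples-by-genes matrices of equal shape with
#'   gene ids as column names.
#' @return Named numeric vector (one MAE per gene).
#' @export
per_gene_mae <- function(truth, prediction) {
  if (!all(dim(truth) == dim(prediction))) {
    stop_dimension("truth and prediction shapes differ")
  }
  colMeans(abs(truth - prediction))
}

as_error_matrix <- function(per_gene_errors) {
  if (is.list(per_gene_errors) && !is.data.frame(per_gene_errors)) {
    gene_sets <- lapply(per_gene_errors, names)
    ref <- gene_sets[[1]]
    if (is.null(ref) || !all(vapply(gene_sets, setequal, logical(1), ref))) {
      stop_schema("all models must report errors for the same named gene set")
    }
    per_gene_errors <- vapply(per_gene_errors, function(e) e[ref],
                              numeric(length(ref)))
    rownames(per_gene_errors) <- ref
  }
  per_gene_errors <- as.matrix(per_gene_errors)
  if (is.null(rownames(per_gene_errors)) || is.null(colnames(per_gene_errors))) {
    stop_schema("error matrix needs gene ids (rows) and model ids (columns)")
  }
  per_gene_errors
}

#' Per-gene expert selection
#'
#' Assigns to each target gene the model with the smallest per-gene mean
#' absolute error on the selection half of the validation data; only that
#' expert is then used to predict the gene.  Exact ties go to the
#' lexicographically smallest model id.
#'
#' @param per_gene_errors Either a genes-by-models numeric matrix (gene ids
#'   as rownames, model ids as colnames) or a named list of named per-gene
#'   error vectors, one per model, all over the same gene set.
#' @return A tibble of class `expert_map` with columns `gene_id` and
#'   `model_id`; the model pool is kept in attribute `"pool"`.
#' @export
per_gene_expert_selection <- function(per_gene_errors) {
  errs <- as_error_matrix(per_gene_errors)
  model_order <- order(colnames(errs))  # lexicographic tie-break
  errs <- errs[, model_order, drop = FALSE]
  pick <- apply(errs, 1, which.min)  # which.min takes the first (smallest id) on ties
  out <- tibble::tibble(gene_id = rownames(errs),
                        model_id = colnames(errs)[pick])
  attr(out, "pool") <- sort(colnames(errs))
  class(out) <- c("expert_map", class(out))
  out
}

#' Predict with a per-gene expert ensemble
#'
#' Column `g` of the output is copied from the prediction matrix of the
#' model mapped to gene `g`.
#'
#' @param expert_map An [per_gene_expert_selection()] result.
#' @param model_predictions Named list of samples-by-genes prediction
#'   matrices (gene ids as column names), one per model in the map.
#' @return Samples-by-genes matrix over the mapped genes, in map order.
#' @export
ensemble_predict <- function(expert_map, model_predictions) {
  needed <- unique(expert_map$model_id)
  missing <- setdiff(needed, names(model_predictions))
  if (length(missing)) {
    stop_schema(sprintf("no predictions for model(s): %s",
                        paste(missing, collapse = ", ")))
  }
  for (m in needed) {
    if (!all(expert_map$gene_id[expert_map$model_id == m] %in%
             colnames(model_predictions[[m]]))) {
      stop_schema(sprintf("model %s predictions do not cover its mapped genes", m))
    }
  }
  first <- model_predictions[[needed[1]]]
  out <- matrix(NA_real_, nrow(first), nrow(expert_map),
                dimnames = list(rownames(first), expert_map$gene_id))
  for (m in needed) {
    genes <- expert_map$gene_id[expert_map$model_id == m]
    out[, genes] <- model_predictions[[m]][, genes, drop = FALSE]
  }
  out
}

#' Write an expert map as two-column tab-delimited text
#'
#' @param expert_map An `expert_map`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_expert_map <- function(expert_map, path) {
  utils::write.table(as.data.frame(expert_map)[, c("gene_id", "model_id")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Enumerate candidate ensembles and select the best
#'
#' Enumerates every non-empty model subset of size at most `max_size`
#' (so `sum(choose(|pool|, 1:max_size))` candidates), builds each subset's
#' per-gene expert map on the *selection* half of the validation data, and
#' ranks the candidates by MMAE on the disjoint *evaluation* half.  The
#' two-stage design means the winner is the best enumerated candidate on
#' the evaluation half, which is not guaranteed to beat every single model
#' there (only on the selection half, where per-gene minimality aggregates).
#'
#' @param truth_sel,truth_eval Ground-truth target matrices for the two
#'   validation halves (disjoint sample sets, gene ids as column names).
#' @param preds_sel,preds_eval Named lists of prediction matrices per model
#'   for the two halves.
#' @param max_size Largest ensemble size considered (default 4).
#' @return A list with `best` (the winning `expert_map`),
#'   `best_models` (its model set), and `ranking` (tibble: `models`,
#'   `n_models`, `mmae_eval`, sorted ascending; ties in lexicographic
#'   model-set order).
#' @export
enumerate_and_select <- function(truth_sel, preds_sel, truth_eval, preds_eval,
                                 max_size = 4) {
  pool <- sort(names(preds_sel))
  if (length(pool) == 0) stop_argument("empty model pool")
  if (!setequal(pool, names(preds_eval))) {
    stop_schema("selection and evaluation predictions cover different pools")
  }
  sel_ids <- rownames(truth_sel); eval_ids <- rownames(truth_eval)
  if (!is.null(sel_ids) && !is.null(eval_ids) &&
      length(intersect(sel_ids, eval_ids)) > 0) {
    stop_argument("selection and evaluation halves overlap")
  }
  sel_errors <- vapply(pool, function(m) per_gene_mae(truth_sel, preds_sel[[m]]),
                       numeric(ncol(truth_sel)))
  rownames(sel_errors) <- colnames(truth_sel)
  subsets <- list()
  for (k in seq_len(min(max_size, length(pool)))) {
    subsets <- c(subsets, utils::combn(pool, k, simplify = FALSE))
  }
  maps <- vector("list", length(subsets))
  mmae_eval <- numeric(length(subsets))
  for (i in seq_along(subsets)) {
    sub <- subsets[[i]]
    maps[[i]] <- per_gene_expert_selection(sel_errors[, sub, drop = FALSE])
    pred <- ensemble_predict(maps[[i]], preds_eval[sub])
    mmae_eval[i] <- mmae(mae_per_sample(
      truth_eval[, colnames(pred), drop = FALSE], pred))
  }
  labels <- vapply(subsets, paste, character(1), collapse = "+")
  ord <- order(mmae_eval, labels)
  best_i <- ord[1]
  list(
    best = maps[[best_i]],
    best_models = subsets[[best_i]],
    ranking = tibble::tibble(models = labels[ord],
                             n_models = lengths(subsets)[ord],
                             mmae_eval = mmae_eval[ord])
  )
}

#' Split validation samples into selection and evaluation halves
#'
#' Seeded 50/50 split of a validation dataset's samples, mirroring the
#' two-stage ensemble-selection protocol (experts chosen on one half,
#' candidate ensembles ranked on the other).
#'
#' @param dataset An [expression_dataset()].
#' @param seed Integer seed.
#' @return Named list of two `expression_dataset`s: `selection`,
#'   `evaluation`.
#' @export
split_validation_halves <- function(dataset, seed = 1) {
  ids <- sort(sample_ids(dataset))
  if (length(ids) < 2) stop_argument("need at least 2 samples")
  perm <- with_seed(seed, sample(ids))
  n1 <- ceiling(length(ids) / 2)
  list(selection = subset_samples(dataset, sort(perm[seq_len(n1)])),
       evaluation = subset_samples(dataset, sort(perm[-seq_len(n1)])))
}
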