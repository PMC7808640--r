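#' Expression dataset with landmark/target gene roles
#'
#' The central data container: a samples-by-genes numeric matrix of
#' (log-scale) expression values, with each gene designated either a
#' *landmark* (measured, network input) or a *target* (inferred, network
#' output), plus optional per-sample series labels (GEO-series-style
#' grouping used for leak-free splitting) and phenotype class labels (used
#' by the differential-expression impact evaluation).
#'
#' @param values Numeric matrix, samples in rows, genes in columns; row and
#'   column names are the sample and gene ids.
#' @param landmark_ids Character vector of gene ids designated landmarks;
#'   all remaining genes are targets.  Both sets must be non-empty.
#' @param series Optional per-sample series labels (character, length
#'   `nrow(values)`; `NA` allowed for samples of unknown series).
#' @param phenotype Optional per-sample class labels.
#' @return An object of class `expression_dataset`.
#' @export
expression_dataset <- function(values, landmark_ids, series = NULL,
                               phenotype = NULL) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop_argument("values must be a numeric matrix")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop_argument("values must carry sample ids (rownames) and gene ids (colnames)")
  }
  if (anyDuplicated(rownames(values))) stop_schema("duplicate sample ids")
  if (anyDuplicated(colnames(values))) stop_schema("duplicate gene ids")
  landmark_ids <- as.character(landmark_ids)
  gene_ids <- colnames(values)
  if (!all(landmark_ids %in% gene_ids)) {
    stop_schema("landmark_ids contains ids absent from the matrix")
  }
  target_ids <- setdiff(gene_ids, landmark_ids)
  if (length(landmark_ids) == 0 || length(target_ids) == 0) {
    stop_schema("landmark and target gene sets must both be non-empty")
  }
  check_sample_vec <- function(x, what) {
    if (is.null(x)) return(NULL)
    if (length(x) != nrow(values)) {
      stop_dimension(sprintf("%s must have one entry per sample", what))
    }
    stats::setNames(as.character(x), rownames(values))
  }
  structure(list(
    values = values,
    landmark_ids = landmark_ids,
    target_ids = target_ids,
    series = check_sample_vec(series, "series"),
    phenotype = check_sample_vec(phenotype, "phenotype")
  ), class = "expression_dataset")
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat(sprintf(
    "<expression_dataset: %d samples x %d genes (%d landmarks, %d targets)%s%s>\n",
    nrow(x$values), ncol(x$values), length(x$landmark_ids),
    length(x$target_ids),
    if (!is.null(x$series)) sprintf(", %d series",
                                    length(unique(stats::na.omit(x$series)))) else "",
    if (!is.null(x$phenotype)) sprintf(", phenotypes {%s}",
                                       paste(sort(unique(x$phenotype)), collapse = ",")) else ""))
  invisible(x)
}

#' @export
dim.expression_dataset <- function(x) dim(x$values)

#' Landmark / target sub-matrices
#'
#' @param dataset An [expression_dataset()].
#' @param gene_ids Optional id subset (and column order) to extract.
#' @return Samples-by-genes numeric matrix.
#' @export
landmark_matrix <- function(dataset, gene_ids = NULL) {
  ids <- gene_ids %||% dataset$landmark_ids
  if (!all(ids %in% dataset$landmark_ids)) stop_schema("unknown landmark ids requested")
  dataset$values[, ids, drop = FALSE]
}

#' @rdname landmark_matrix
#' @export
target_matrix <- function(dataset, gene_ids = NULL) {
  ids <- gene_ids %||% dataset$target_ids
  if (!all(ids %in% dataset$target_ids)) stop_schema("unknown target ids requested")
  dataset$values[, ids, drop = FALSE]
}

sample_ids <- function(dataset) rownames(dataset$values)

subset_samples <- function(dataset, ids) {
  structure(list(
    values = dataset$values[ids, , drop = FALSE],
    landmark_ids = dataset$landmark_ids,
    target_ids = dataset$target_ids,
    series = if (!is.null(dataset$series)) dataset$series[ids],
    phenotype = if (!is.null(dataset$phenotype)) dataset$phenotype[ids]
  ), class = "expression_dataset")
}

#' Long-format view of an expression dataset
#'
#' @param x An [expression_dataset()].
#' @param ... Unused.
#' @return A tibble with columns `sample_id`, `gene_id`, `role`, `value`
#'   and, when present, `series` and `phenotype`.
#' @export
as_tibble.expression_dataset <- function(x, ...) {
  out <- tibble::tibble(
    sample_id = rep(rownames(x$values), times = ncol(x$values)),
    gene_id = rep(colnames(x$values), each = nrow(x$values)),
    value = as.vector(x$values)
  )
  out$role <- ifelse(out$gene_id %in% x$landmark_ids, "landmark", "target")
  if (!is.null(x$series)) out$series <- x$series[out$sample_id]
  if (!is.null(x$phenotype)) out$phenotype <- x$phenotype[out$sample_id]
  out
}

#' Whole-matrix (global) standardization
#'
#' Standardizes the *entire* expression matrix to zero mean and unit
#' standard deviation using one global mean and one global (population)
#' standard deviation — deliberately *not* per gene.  Per-gene scaling would
#' erase absolute expression differences between genes and give
#' noise-level genes the same weight as highly expressed ones in the error
#' metrics; global scaling keeps more-expressed genes proportionately
#' larger after standardization.
#'
#' @param dataset An [expression_dataset()].
#' @return A list with elements `dataset` (standardized copy) and `scaler`
#'   (class `global_scaler`, fields `mean` and `sd`).
#' @export
global_standardize <- function(dataset) {
  x <- dataset$values
  if (sum(is.finite(x)) < 2) stop_argument("need at least 2 finite values")
  m <- mean(x)
  s <- sqrt(mean((x - m)^2))  # population sd over all entries
  if (!is.finite(s) || s <= 0) {
    stop_degenerate("matrix is constant; global standardization is undefined")
  }
  out <- dataset
  out$values <- (x - m) / s
  list(dataset = out,
       scaler = structure(list(mean = m, sd = s), class = "global_scaler"))
}

#' Invert a global standardization
#'
#' @param x Standardized [expression_dataset()] or numeric matrix.
#' @param scaler The `global_scaler` returned by [global_standardize()].
#' @return Object of the same type on the original scale.
#' @export
inverse_standardize <- function(x, scaler) {
  if (inherits(x, "expression_dataset")) {
    x$values <- x$values * scaler$sd + scaler$mean
    x
  } else {
    x * scaler$sd + scaler$mean
  }
}

# largest-remainder rounding of n into parts proportional to fractions;
# leftover units go to the largest fractional remainders, earlier part wins
# ties
largest_remainder_sizes <- function(n, fractions) {
  raw <- n * fractions
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    frac <- raw - base
    ord <- order(-frac, seq_along(frac))  # ties -> earlier split
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1
  }
  as.integer(base)
}

check_fractions <- function(fractions) {
  if (length(fractions) != 3 || any(!is.finite(fractions)) ||
      any(fractions <= 0) || abs(sum(fractions) - 1) > 1e-8) {
    stop_argument("fractions must be three positive reals summing to 1")
  }
  fractions
}

#' Random train/validation/test split
#'
#' Samples are split into three disjoint, exhaustive subsets whose sizes
#' follow the requested fractions under largest-remainder rounding (ties
#' favor the earlier split).  Sample ids are sorted lexicographically before
#' the seeded shuffle, so the split depends on the id set only, not on row
#' order.
#'
#' @param dataset An [expression_dataset()] with at least 3 samples.
#' @param fractions Train/validation/test fractions (positive, summing to 1).
#' @param seed Integer seed.
#' @return Named list of three `expression_dataset`s:
#'   `train`, `validation`, `test`.
#' @export
random_split <- function(dataset, fractions = c(0.7, 0.15, 0.15), seed = 1) {
  fractions <- check_fractions(fractions)
  ids <- sort(sample_ids(dataset))
  n <- length(ids)
  if (n < 3) stop_argument("need at least 3 samples to split")
  sizes <- largest_remainder_sizes(n, fractions)
  perm <- with_seed(seed, sample(ids))
  bounds <- cumsum(sizes)
  list(
    train = subset_samples(dataset, sort(perm[seq_len(bounds[1])])),
    validation = subset_samples(dataset, sort(perm[(bounds[1] + 1):bounds[2]])),
    test = subset_samples(dataset, sort(perm[(bounds[2] + 1):bounds[3]]))
  )
}

#' Heterogeneity-aware (series-grouped) split
#'
#' Splits samples so that no series contributes samples to more than one of
#' the train/validation/test subsets, eliminating series-level information
#' leakage between them.  Samples without a series label are excluded first.
#' Series are assigned greedily, largest first, each to the split with the
#' largest remaining sample deficit; with many small series the realized
#' fractions track the targets closely, and a warning is raised when the
#' realized fractions deviate from the targets by more than 5 percentage
#' points (e.g. when one giant series dominates).
#'
#' @inheritParams random_split
#' @return Named list of three `expression_dataset`s.  The realized
#'   fractions are attached as attribute `"realized_fractions"`.
#' @export
group_aware_split <- function(dataset, fractions = c(0.7, 0.15, 0.15), seed = 1) {
  fractions <- check_fractions(fractions)
  if (is.null(dataset$series)) {
    stop_schema("dataset has no series labels; use random_split instead")
  }
  keep <- sample_ids(dataset)[!is.na(dataset$series[sample_ids(dataset)])]
  if (length(keep) < length(sample_ids(dataset))) {
    message(sprintf("excluding %d samples without a series label",
                    length(sample_ids(dataset)) - length(keep)))
  }
  series <- dataset$series[sort(keep)]
  sizes <- table(series)
  if (length(sizes) < 3) stop_infeasible("need at least 3 series for a grouped 3-way split")
  # deterministic order: seeded shuffle of labels, then stable sort by size
  # descending — equally sized series are ordered by the seed
  labels <- with_seed(seed, sample(names(sizes)))
  labels <- labels[order(-as.integer(sizes[labels]))]
  n_total <- length(keep)
  target_n <- n_total * fractions
  assigned <- c(0, 0, 0)
  split_of <- stats::setNames(integer(length(labels)), labels)
  for (lab in labels) {
    deficit <- target_n - assigned
    pick <- which.max(deficit)  # ties -> earlier split (train, validation, test)
    split_of[lab] <- pick
    assigned[pick] <- assigned[pick] + as.integer(sizes[lab])
  }
  realized <- assigned / n_total
  if (max(abs(realized - fractions)) > 0.05) {
    warning(sprintf(
      "realized split fractions (%.3f/%.3f/%.3f) deviate from targets by more than 5 points (dominant series?)",
      realized[1], realized[2], realized[3]))
  }
  ids_of <- function(k) {
    labs <- names(split_of)[split_of == k]
    sort(names(series)[series %in% labs])
  }
  out <- list(train = subset_samples(dataset, ids_of(1)),
              validation = subset_samples(dataset, ids_of(2)),
              test = subset_samples(dataset, ids_of(3)))
  attr(out, "realized_fractions") <- realized
  out
}

# ---------------------------------------------------------------------------
# file formats

#' Read an expression matrix
#'
#' Two plain-text dialects are supported. GCT v1.2: first line `#1.2`,
#' second line `<n_genes>\t<n_samples>`, then a header row
#' (`NAME`, `Description`, sample ids) and one row per gene.  TSV: samples
#' in rows, first column `sample_id`, remaining header fields are gene ids.
#' Gene roles are supplied by a companion landmark-id list file (one id per
#' line).
#'
#' @param path Expression file.
#' @param landmark_file Path to the landmark id list.
#' @param format `"gct"`, `"tsv"`, or `"auto"` (by extension / header sniff).
#' @param series,phenotype Optional per-sample metadata vectors, passed to
#'   [expression_dataset()].
#' @return An [expression_dataset()].
#' @export
read_expression <- function(path, landmark_file,
                            format = c("auto", "gct", "tsv"),
                            series = NULL, phenotype = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    first <- readLines(path, n = 1)
    format <- if (startsWith(first, "#1.2")) "gct" else "tsv"
  }
  values <- if (format == "gct") read_gct_matrix(path) else read_tsv_matrix(path)
  landmark_ids <- read_id_list(landmark_file)
  expression_dataset(values, landmark_ids, series = series,
                     phenotype = phenotype)
}

read_gct_matrix <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 3) stop_format("GCT file truncated (line 1)")
  if (trimws(lines[1]) != "#1.2") {
    stop_format("line 1: expected GCT version tag '#1.2'")
  }
  dims <- strsplit(lines[2], "\t", fixed = TRUE)[[1]]
  if (length(dims) < 2 || anyNA(suppressWarnings(as.integer(dims[1:2])))) {
    stop_format("line 2: expected '<n_genes>\\t<n_samples>'")
  }
  n_genes <- as.integer(dims[1]); n_samples <- as.integer(dims[2])
  header <- strsplit(lines[3], "\t", fixed = TRUE)[[1]]
  if (length(header) != n_samples + 2) {
    stop_format(sprintf("line 3: header has %d sample columns, dimensions line declares %d",
                        length(header) - 2, n_samples))
  }
  samples <- header[-(1:2)]
  body <- lines[-(1:3)]
  body <- body[nzchar(body)]
  if (length(body) != n_genes) {
    stop_format(sprintf("line %d: found %d gene rows, dimensions line declares %d",
                        length(lines), length(body), n_genes))
  }
  fields <- strsplit(body, "\t", fixed = TRUE)
  ragged <- which(lengths(fields) != n_samples + 2)
  if (length(ragged)) {
    stop_format(sprintf("line %d: row has %d fields, expected %d",
                        ragged[1] + 3, lengths(fields)[ragged[1]], n_samples + 2))
  }
  genes <- vapply(fields, `[[`, character(1), 1)
  if (anyDuplicated(genes)) {
    stop_format(sprintf("duplicate gene id '%s'", genes[duplicated(genes)][1]))
  }
  if (anyDuplicated(samples)) {
    stop_format(sprintf("duplicate sample id '%s'", samples[duplicated(samples)][1]))
  }
  vals <- vapply(fields, function(f) as.numeric(f[-(1:2)]), numeric(n_samples))
  # vals is samples x genes already (vapply binds by column)
  mat <- matrix(vals, nrow = n_samples, ncol = n_genes,
                dimnames = list(samples, genes))
  mat
}

read_tsv_matrix <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 2) stop_format("TSV file truncated (line 1)")
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  genes <- header[-1]
  if (anyDuplicated(genes)) {
    stop_format(sprintf("duplicate gene column '%s'",
                        paste(unique(genes[duplicated(genes)]), collapse = "', '")))
  }
  body <- lines[-1]
  body <- body[nzchar(body)]
  fields <- strsplit(body, "\t", fixed = TRUE)
  ragged <- which(lengths(fields) != length(header))
  if (length(ragged)) {
    stop_format(sprintf("line %d: row has %d fields, expected %d",
                        ragged[1] + 1, lengths(fields)[ragged[1]], length(header)))
  }
  samples <- vapply(fields, `[[`, character(1), 1)
  if (anyDuplicated(samples)) {
    stop_format(sprintf("duplicate sample id '%s'", samples[duplicated(samples)][1]))
  }
  vals <- t(vapply(fields, function(f) as.numeric(f[-1]), numeric(length(genes))))
  matrix(vals, nrow = length(samples), ncol = length(genes),
         dimnames = list(samples, genes))
}

#' Write an expression matrix
#'
#' @param dataset An [expression_dataset()].
#' @param path Output file.
#' @param format `"gct"` or `"tsv"` (see [read_expression()] for the
#'   dialects).
#' @param landmark_file Optional path; when given, the landmark id list is
#'   written there (one id per line).
#' @return `path`, invisibly.
#' @export
write_expression <- function(dataset, path, format = c("gct", "tsv"),
                             landmark_file = NULL) {
  format <- match.arg(format)
  x <- dataset$values
  if (format == "gct") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("#1.2", paste(ncol(x), nrow(x), sep = "\t")), con)
    writeLines(paste(c("NAME", "Description", rownames(x)), collapse = "\t"), con)
    tx <- t(x)  # genes in rows
    rows <- paste(colnames(x), "na",
                  apply(tx, 1, function(r) paste(format(r, digits = 15, trim = TRUE),
                                                 collapse = "\t")),
                  sep = "\t")
    writeLines(rows, con)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste(c("sample_id", colnames(x)), collapse = "\t"), con)
    rows <- paste(rownames(x),
                  apply(x, 1, function(r) paste(format(r, digits = 15, trim = TRUE),
                                                collapse = "\t")),
                  sep = "\t")
    writeLines(rows, con)
  }
  if (!is.null(landmark_file)) write_id_list(dataset$landmark_ids, landmark_file)
  invisible(path)
}

#' Read / write an id list file (one id per line)
#'
#' Used for the landmark-gene list and for split manifests.
#'
#' @param path File path.
#' @return Character vector of ids.
#' @export
read_id_list <- function(path) {
  ids <- readLines(path)
  ids <- trimws(ids)
  ids[nzchar(ids)]
}

#' @rdname read_id_list
#' @param ids Character vector to write.
#' @export
write_id_list <- function(ids, path) {
  writeLines(as.character(ids), path)
  invisible(path)
}
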