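#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom tibble as_tibble
#' @export
tibble::as_tibble

#' Tidy a network training history
#'
#' @param x A [train_network()] fit.
#' @param ... Unused.
#' @return Tibble with columns `epoch`, `train_loss`, `val_mmae`, `best`.
#' @export
tidy.dgex_fit <- function(x, ...) {
  out <- x$history
  out$best <- out$epoch == x$best_epoch
  out
}

#' One-row summary of a network fit
#'
#' @param x A [train_network()] fit.
#' @param ... Unused.
#' @return Tibble: `n_epochs`, `best_epoch`, `best_val_mmae`,
#'   `final_train_loss`, `n_parameters`.
#' @export
glance.dgex_fit <- function(x, ...) {
  tibble::tibble(
    n_epochs = nrow(x$history),
    best_epoch = x$best_epoch,
    best_val_mmae = min(x$history$val_mmae),
    final_train_loss = x$history$train_loss[nrow(x$history)],
    n_parameters = parameter_count(x$network$spec)
  )
}

#' Learning curves of a network fit
#'
#' Training loss and validation MMAE per epoch, with the selected best
#' epoch marked.
#'
#' @param object A [train_network()] fit.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.dgex_fit <- function(object, ...) {
  df <- tidyr::pivot_longer(tidy(object), c("train_loss", "val_mmae"),
                            names_to = "curve", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$value,
                                   colour = .data$curve)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$best_epoch, linetype = "dotted") +
    ggplot2::labs(x = "epoch", y = NULL, colour = NULL,
                  title = "Training history",
                  subtitle = sprintf("best epoch %d (validation MMAE %.4f)",
                                     object$best_epoch,
                                     min(object$history$val_mmae))) +
    ggplot2::theme_minimal()
}

#' Tidy / summarize a model comparison
#'
#' @param x A [compare_models()] result.
#' @param ... Unused.
#' @return `tidy()`: the comparison tibble.  `glance()`: one row with the
#'   point estimate, interval width and minimum p-value.
#' @export
tidy.model_comparison <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' @rdname tidy.model_comparison
#' @export
glance.model_comparison <- function(x, ...) {
  tibble::tibble(
    mmdae = x$mmdae,
    ci_width = x$ci_high - x$ci_low,
    min_p = pmin(x$t_test_p, x$wilcoxon_p),
    favors = ifelse(x$mmdae < 0, x$model_1, x$model_2)
  )
}

#' Tidy / summarize a DGE impact evaluation
#'
#' @param x A [subsample_experiment()] result.
#' @param ... Unused.
#' @return `tidy()`: the long per-repetition results.  `glance()`: median
#'   score per method, size and metric.
#' @export
tidy.dge_eval <- function(x, ...) x$results

#' @rdname tidy.dge_eval
#' @export
glance.dge_eval <- function(x, ...) {
  dplyr::summarise(
    dplyr::group_by(x$results, .data$method, .data$size, .data$metric),
    median = stats::median(.data$value, na.rm = TRUE),
    .groups = "drop")
}

#' Score distributions across subsample sizes
#'
#' Boxplots of a chosen metric per method and sample size, the standard
#' view of the downstream DGE-impact comparison.
#'
#' @param object A [subsample_experiment()] result.
#' @param metric Which metric to draw (default `"f_1"`).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.dge_eval <- function(object, metric = "f_1", ...) {
  df <- object$results[object$results$metric == metric, ]
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$size), y = .data$value,
                                   fill = .data$method)) +
    ggplot2::geom_boxplot(outlier.size = 0.4) +
    ggplot2::labs(x = "subsample size", y = metric,
                  title = "DE recovery across study sizes") +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
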