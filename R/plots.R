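#' Plot methods
#'
#' `autoplot()` methods for the package's result objects: the training-loss
#' curve of a `ppd_fit`, the accuracy distributions of a `ppd_benchmark`,
#' and the correlation heatmap of a `ppd_summary`. `plot_metrics()` draws a
#' grouped bar chart from any tibble of metric reports (e.g. the output of
#' [ablate()] or [split_sweep()]).
#'
#' @param object A `ppd_fit`, `ppd_benchmark` or `ppd_summary`.
#' @param ... Unused.
#' @return A ggplot object.
#' @name ppdens-plots
NULL

#' @rdname ppdens-plots
#' @method autoplot ppd_fit
#' @export
autoplot.ppd_fit <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$epoch,
                                             y = .data$loss)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::labs(x = "epoch", y = "mean squared-error loss",
                  title = sprintf("Training loss (dropout = %.2f)",
                                  object$network$dropout_rate)) +
    ggplot2::theme_minimal()
}

#' @rdname ppdens-plots
#' @method autoplot ppd_benchmark
#' @export
autoplot.ppd_benchmark <- function(object, ...) {
  df <- purrr::imap_dfr(object$runs, function(acc, name) {
    tibble(model = name, accuracy = acc)
  })
  ggplot2::ggplot(df, ggplot2::aes(x = .data$model, y = .data$accuracy)) +
    ggplot2::geom_boxplot(fill = "grey90") +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.4, size = 0.8) +
    ggplot2::labs(x = NULL, y = "test accuracy",
                  title = "Repeated-run accuracy by classifier") +
    ggplot2::theme_minimal()
}

#' @rdname ppdens-plots
#' @method autoplot ppd_summary
#' @export
autoplot.ppd_summary <- function(object, ...) {
  R <- object$correlations
  df <- as_tibble(as.data.frame.table(R, responseName = "r"))
  names(df)[1:2] <- c("x", "y")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "Pearson r",
                  title = "Pairwise feature correlations") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' @rdname ppdens-plots
#' @param data A tibble with a `model` column and the nine metric columns.
#' @export
plot_metrics <- function(data, ...) {
  metric_cols <- intersect(
    c("accuracy", "precision", "recall", "f1", "mcc", "specificity",
      "npv", "fpr", "fnr"), names(data))
  long <- tidyr::pivot_longer(data, dplyr::all_of(metric_cols),
                              names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$metric, y = .data$value,
                                     fill = .data$model)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = NULL, fill = "model") +
    ggplot2::theme_minimal()
}
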