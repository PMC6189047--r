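#' Plot training curves of a fitted classifier
#'
#' Mean training loss and validation AUC per epoch, with the restored
#' best epoch marked.
#'
#' @param object A `bigru_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.bigru_fit <- function(object, ...) {
  h <- tidyr::pivot_longer(object$history, c("loss", "val_auc"),
                           names_to = "metric", values_to = "value")
  ggplot2::ggplot(h, ggplot2::aes(x = .data$epoch, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_vline(xintercept = object$best_epoch, linetype = "dashed",
                        colour = "grey40") +
    ggplot2::facet_wrap(~metric, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "epoch", y = NULL,
                  title = "Training loss and validation AUC",
                  subtitle = paste0("dashed line: restored epoch ",
                                    object$best_epoch)) +
    ggplot2::theme_minimal()
}

#' Plot a hyper-parameter grid as a units-by-optimizer heat map
#'
#' @param object A `bigru_grid`.
#' @param metric `"auc"` (default) or `"aps"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.bigru_grid <- function(object, metric = c("auc", "aps"), ...) {
  metric <- match.arg(metric)
  r <- object$report
  ggplot2::ggplot(r, ggplot2::aes(x = .data$optimizer,
                                  y = factor(.data$units),
                                  fill = .data[[metric]])) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(
      label = ifelse(is.na(.data[[metric]]), "fail",
                     sprintf("%.3f", .data[[metric]]))), size = 3) +
    ggplot2::scale_fill_viridis_c(na.value = "grey80") +
    ggplot2::labs(x = "optimizer", y = "GRU units",
                  fill = paste("validation", metric),
                  title = "Hyper-parameter grid") +
    ggplot2::theme_minimal()
}

#' Plot an embedding-strategy comparison
#'
#' @param object A `bigru_ablation` tibble from
#'   [compare_embedding_strategies()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.bigru_ablation <- function(object, ...) {
  h <- tidyr::pivot_longer(object, c("auc", "aps"),
                           names_to = "metric", values_to = "value")
  ggplot2::ggplot(h, ggplot2::aes(x = .data$strategy, y = .data$value,
                                  fill = .data$split)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~metric) +
    ggplot2::labs(x = "embedding strategy", y = NULL,
                  title = "Effect of the embedding strategy") +
    ggplot2::theme_minimal()
}

#' Plot a sensitivity sweep
#'
#' @param object A `bigru_sweep` tibble from [sensitivity_sweep()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.bigru_sweep <- function(object, ...) {
  h <- tidyr::pivot_longer(object, c("mean_auc", "median_auc"),
                           names_to = "summary", values_to = "auc")
  ggplot2::ggplot(h, ggplot2::aes(x = .data$value, y = .data$auc,
                                  linetype = .data$summary)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = unique(object$axis), y = "test AUC",
                  title = paste("Sensitivity to", unique(object$axis))) +
    ggplot2::theme_minimal()
}
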