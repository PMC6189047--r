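#' Tidy a fitted classifier's training history
#'
#' @param x A `bigru_fit`.
#' @param ... Unused.
#' @return A tibble with one row per epoch: `epoch`, `loss` (mean training
#'   loss per sequence), `val_auc`.
#' @export
tidy.bigru_fit <- function(x, ...) x$history

#' One-row summary of a fitted classifier
#'
#' @param x A `bigru_fit`.
#' @param ... Unused.
#' @return A one-row tibble: units, optimizer, embedding strategy,
#'   epochs run, best epoch, validation AUC at the restored weights and
#'   parameter count.
#' @export
glance.bigru_fit <- function(x, ...) {
  n_par <- sum(vapply(model_flat_params(x$model), length, integer(1)))
  tibble::tibble(
    units = x$config$units,
    optimizer = x$config$optimizer,
    embedding_strategy = x$config$embedding_strategy,
    merge_mode = x$config$merge_mode,
    epochs_run = nrow(x$history),
    best_epoch = x$best_epoch,
    val_auc = x$val_auc,
    n_parameters = n_par
  )
}

#' Tidy a grid-search result
#'
#' @param x A `bigru_grid`.
#' @param ... Unused.
#' @return The per-cell report tibble (one row per configuration).
#' @export
tidy.bigru_grid <- function(x, ...) x$report

#' One-row summary of a grid search
#'
#' @param x A `bigru_grid`.
#' @param ... Unused.
#' @return A one-row tibble describing the selected configuration and its
#'   validation and test metrics.
#' @export
glance.bigru_grid <- function(x, ...) {
  tibble::tibble(
    n_cells = nrow(x$report),
    n_failed = sum(x$report$status != "ok"),
    best_units = x$best_config$units,
    best_optimizer = x$best_config$optimizer,
    val_auc = x$report$auc[x$best_index],
    val_aps = x$report$aps[x$best_index],
    test_auc = x$test_metrics$auc,
    test_aps = x$test_metrics$aps
  )
}
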