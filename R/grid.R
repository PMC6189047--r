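#' The default hyper-parameter grid
#'
#' Crosses GRU units \{50, 80, 100\} with optimizers \{SGD, Adam, Adagrad,
#' RMSprop\}: 12 configurations, each otherwise identical to `base`.
#'
#' @param base A [train_config()] supplying every other field.
#' @param units Units values (default `c(50, 80, 100)`).
#' @param optimizers Optimizer names (default all four).
#' @return A list of `train_config` objects.
#' @export
default_grid <- function(base = train_config(),
                         units = c(50L, 80L, 100L),
                         optimizers = c("SGD", "Adam", "Adagrad", "RMSprop")) {
  cells <- expand.grid(units = units, optimizer = optimizers,
                       stringsAsFactors = FALSE)
  purrr::pmap(cells, function(units, optimizer) {
    cfg <- base
    cfg$units <- as.integer(units)
    cfg$optimizer <- optimizer
    cfg$learning_rate <- optimizer_default_lr[[optimizer]]
    cfg
  })
}

config_row <- function(cfg) {
  tibble::tibble(
    units = cfg$units, optimizer = cfg$optimizer,
    batch_size = cfg$batch_size, epochs = cfg$epochs,
    learning_rate = cfg$learning_rate,
    embedding_strategy = cfg$embedding_strategy,
    k = cfg$k, s = cfg$s, d = cfg$d, merge_mode = cfg$merge_mode,
    seed = cfg$seed
  )
}

#' Train and evaluate every configuration of a hyper-parameter grid
#'
#' Fits one model per grid cell, scores it on the validation split, and
#' selects the best cell by validation AUC (ties broken by higher APS,
#' then smaller units). Test metrics are reported for the selected cell.
#' A cell whose training fails is flagged in the report and does not abort
#' the remaining cells.
#'
#' @param data A labelled dataset with a `split` column (or one is derived
#'   from the base seed).
#' @param grid A list of [train_config()]s; default [default_grid()].
#' @param pretrained Optional shared `kmer_embedding`. When `NULL` and any
#'   cell needs one, a single embedding is pre-trained once (all default
#'   cells share `k`, `s`, `d`) and reused across cells.
#' @param verbose Print progress per cell.
#' @return A `bigru_grid` object: `report` (one row per cell with
#'   validation `auc`/`aps` and `status`), `best_config`, `best_fit` and
#'   `test_metrics` for the selected cell.
#' @export
grid_search <- function(data, grid = default_grid(), pretrained = NULL,
                        verbose = FALSE) {
  if (length(grid) == 0) abort("grid_search: empty grid")
  validate_dataset(data)
  if (!"split" %in% names(data)) {
    data <- split_dataset(data, seed = derive_seed(grid[[1]]$seed, "split"))
  }
  if (is.null(pretrained)) {
    needs <- vapply(grid, function(g) g$embedding_strategy != "no_init",
                    logical(1))
    kds <- unique(t(vapply(grid, function(g) c(g$k, g$s, g$d), integer(3))))
    if (any(needs) && nrow(kds) == 1) {
      g1 <- grid[[which(needs)[1]]]
      corpus <- build_corpus(data[data$split == "train", ], k = g1$k, s = g1$s)
      pretrained <- train_kmer_embedding(
        corpus, vocab = kmer_vocab(g1$k), d = g1$d,
        seed = derive_seed(g1$seed, "embedding")
      )
    }
  }
  rows <- vector("list", length(grid))
  fits <- vector("list", length(grid))
  for (i in seq_along(grid)) {
    cfg <- grid[[i]]
    res <- tryCatch({
      fit <- fit_bigru(data, cfg, pretrained = pretrained)
      ev <- evaluate_model(fit, data, split = "validation")
      fits[[i]] <- fit
      dplyr::bind_cols(config_row(cfg),
                       tibble::tibble(split = "validation", auc = ev$auc,
                                      aps = ev$aps, status = "ok"))
    }, error = function(e) {
      dplyr::bind_cols(config_row(cfg),
                       tibble::tibble(split = "validation", auc = NA_real_,
                                      aps = NA_real_,
                                      status = paste0("failed: ",
                                                      conditionMessage(e))))
    })
    rows[[i]] <- res
    if (verbose) {
      message(sprintf("grid cell %d/%d  units=%s opt=%s  auc=%s", i,
                      length(grid), cfg$units, cfg$optimizer,
                      format(res$auc, digits = 4)))
    }
  }
  report <- dplyr::bind_rows(rows)
  ok <- which(report$status == "ok")
  if (length(ok) == 0) abort("grid_search: every grid cell failed")
  sel <- ok[order(-report$auc[ok], -report$aps[ok], report$units[ok])][1]
  best_fit <- fits[[sel]]
  test_metrics <- evaluate_model(best_fit, data, split = "test")
  structure(
    list(report = report, best_config = grid[[sel]], best_fit = best_fit,
         best_index = sel, test_metrics = test_metrics),
    class = "bigru_grid"
  )
}

#' @export
print.bigru_grid <- function(x, ...) {
  cat("<bigru_grid>", nrow(x$report), "cells; best: units =",
      x$best_config$units, "optimizer =", x$best_config$optimizer,
      sprintf("(val AUC %.4f)\n", x$report$auc[x$best_index]))
  invisible(x)
}

#' Compare the three embedding-layer strategies
#'
#' Trains one model per strategy — `no_init` (random, trainable),
#' `init_no_train` (pretrained, frozen), `init_train` (pretrained,
#' fine-tuned) — with an otherwise identical configuration and seed, and
#' reports validation and test AUC and APS side by side.
#'
#' @param data A labelled dataset (split derived from the config seed if
#'   absent).
#' @param config Base [train_config()]; its `embedding_strategy` field is
#'   overridden per run.
#' @param pretrained A `kmer_embedding`; trained from the training corpus
#'   when `NULL`.
#' @return A tibble with one row per strategy and split (class
#'   `bigru_ablation`).
#' @export
compare_embedding_strategies <- function(data, config = train_config(),
                                         pretrained = NULL) {
  validate_dataset(data)
  if (!"split" %in% names(data)) {
    data <- split_dataset(data, seed = derive_seed(config$seed, "split"))
  }
  if (is.null(pretrained)) {
    corpus <- build_corpus(data[data$split == "train", ],
                           k = config$k, s = config$s)
    pretrained <- train_kmer_embedding(
      corpus, vocab = kmer_vocab(config$k), d = config$d,
      seed = derive_seed(config$seed, "embedding")
    )
  }
  rows <- lapply(c("no_init", "init_no_train", "init_train"), function(st) {
    cfg <- config
    cfg$embedding_strategy <- st
    fit <- fit_bigru(data, cfg, pretrained = pretrained)
    dplyr::bind_cols(
      tibble::tibble(strategy = st),
      dplyr::bind_rows(evaluate_model(fit, data, "validation"),
                       evaluate_model(fit, data, "test"))
    )
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("bigru_ablation", class(out))
  out
}

#' Sensitivity sweep over k, stride or embedding dimension
#'
#' Re-runs the full pipeline for each value of one axis: `k` and `s`
#' change the k-mer corpus (the embedding is re-trained), `d` changes the
#' embedding dimension. The remaining configuration is held fixed. Mean
#' and median test AUC over `n_seeds` replicate seeds are reported per
#' value.
#'
#' @param data A labelled dataset.
#' @param axis One of `"k"`, `"s"`, `"d"`.
#' @param values Axis values (canonical sweeps: k 4-6, s 2-5,
#'   d 50/100/150/200).
#' @param config Base [train_config()].
#' @param n_seeds Replicate seeds per value (default 1).
#' @return A tibble (class `bigru_sweep`) with one row per value:
#'   `axis`, `value`, `vocab_size`, `mean_auc`, `median_auc`, `mean_aps`.
#' @export
sensitivity_sweep <- function(data, axis = c("k", "s", "d"), values,
                              config = train_config(), n_seeds = 1L) {
  axis <- match.arg(axis)
  if (length(values) == 0) abort("sensitivity_sweep: no values")
  validate_dataset(data)
  if (!"split" %in% names(data)) {
    data <- split_dataset(data, seed = derive_seed(config$seed, "split"))
  }
  rows <- lapply(values, function(v) {
    cfg <- config
    cfg[[axis]] <- as.integer(v)
    runs <- lapply(seq_len(n_seeds), function(i) {
      cfg$seed <- derive_seed(config$seed, paste0(axis, v, "rep", i))
      fit <- fit_bigru(data, cfg)
      evaluate_model(fit, data, "test")
    })
    aucs <- vapply(runs, function(r) r$auc, numeric(1))
    apss <- vapply(runs, function(r) r$aps, numeric(1))
    tibble::tibble(
      axis = axis, value = as.integer(v),
      vocab_size = 4L^cfg$k,
      n_seeds = n_seeds,
      mean_auc = mean(aucs), median_auc = stats::median(aucs),
      mean_aps = mean(apss)
    )
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("bigru_sweep", class(out))
  out
}
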