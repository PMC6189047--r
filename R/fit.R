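#' Build a training configuration
#'
#' One cell of the hyper-parameter space: GRU size and optimizer (the
#' default grid crosses units 50/80/100 with SGD, Adam, Adagrad and
#' RMSprop), mini-batch size (default 200), tokenisation (`k = 5`,
#' `s = 2`), embedding dimension (`d = 50`) and strategy, merge mode and
#' seed. Optimizer learning rates default to SGD 0.01, Adam 0.001,
#' Adagrad 0.01, RMSprop 0.001.
#'
#' @param units GRU hidden size per direction.
#' @param optimizer One of `"SGD"`, `"Adam"`, `"Adagrad"`, `"RMSprop"`.
#' @param batch_size Mini-batch size, `>= 1` (default 200).
#' @param epochs Maximum training epochs, `>= 1` (default 20).
#' @param learning_rate Optional override of the optimizer default.
#' @param embedding_strategy `"init_train"` (default), `"no_init"` or
#'   `"init_no_train"`.
#' @param k,s K-mer length and stride (defaults 5 and 2).
#' @param d Embedding dimension (default 50).
#' @param merge_mode Direction merge: `"concatenate"` (default), `"sum"`,
#'   `"average"` or `"multiplication"`.
#' @param head_input `"final"` (default) or `"mean_pool"`.
#' @param n_layers Stacked bidirectional layers (default 1).
#' @param patience Early-stopping patience on validation AUC (default 5);
#'   `Inf` disables early stopping.
#' @param seed Root seed; component seeds (split, embedding, weight init,
#'   batch order) are derived from it.
#' @return A `train_config` object.
#' @export
train_config <- function(units = 50L, optimizer = "Adam", batch_size = 200L,
                         epochs = 20L, learning_rate = NULL,
                         embedding_strategy = "init_train",
                         k = 5L, s = 2L, d = 50L,
                         merge_mode = "concatenate",
                         head_input = "final", n_layers = 1L,
                         patience = 5, seed = 1L) {
  if (!optimizer %in% names(optimizer_default_lr)) {
    abort(paste0("unknown optimizer: ", optimizer))
  }
  if (!embedding_strategy %in% c("no_init", "init_no_train", "init_train")) {
    abort(paste0("unknown embedding strategy: ", embedding_strategy))
  }
  if (!merge_mode %in% c("concatenate", "sum", "average", "multiplication")) {
    abort(paste0("unknown merge mode: ", merge_mode))
  }
  batch_size <- as.integer(batch_size)
  epochs <- as.integer(epochs)
  if (is.na(epochs) || epochs < 1) abort("epochs must be >= 1")
  if (is.na(batch_size) || batch_size < 1) abort("batch_size must be >= 1")
  if (as.integer(units) < 1) abort("units must be >= 1")
  structure(
    list(
      units = as.integer(units), optimizer = optimizer,
      batch_size = batch_size, epochs = epochs,
      learning_rate = learning_rate %||% optimizer_default_lr[[optimizer]],
      embedding_strategy = embedding_strategy,
      k = as.integer(k), s = as.integer(s), d = as.integer(d),
      merge_mode = merge_mode, head_input = head_input,
      n_layers = as.integer(n_layers), patience = patience,
      seed = as.integer(seed)
    ),
    class = "train_config"
  )
}

#' @export
print.train_config <- function(x, ...) {
  cat("<train_config>", paste0(
    "units=", x$units, " opt=", x$optimizer, " lr=", x$learning_rate,
    " batch=", x$batch_size, " epochs=", x$epochs,
    " strategy=", x$embedding_strategy,
    " k=", x$k, " s=", x$s, " d=", x$d,
    " merge=", x$merge_mode, " seed=", x$seed
  ), "\n")
  invisible(x)
}

#' Train a bidirectional GRU binding-site classifier
#'
#' Tokenizes the sequences with the configured `k` and `s`, prepares the
#' embedding layer per the configured strategy (pre-training k-mer vectors
#' on the training-split corpus when needed and none are supplied), and
#' minimises the Bernoulli negative log-likelihood by mini-batch gradient
#' descent. Each epoch logs the mean training loss and validation AUC;
#' training stops early after `patience` epochs without validation
#' improvement and the weights of the best-validation-AUC epoch are
#' restored.
#'
#' @param data A labelled dataset tibble. If it has no `split` column it is
#'   partitioned 0.8/0.1/0.1 (stratified) under a seed derived from
#'   `config$seed`.
#' @param config A [train_config()].
#' @param pretrained Optional `kmer_embedding` used by the `init_*`
#'   strategies; when `NULL` and needed, one is trained from the
#'   training-split corpus.
#' @param verbose Print per-epoch progress.
#' @return A `bigru_fit`: the trained `model`, the `config`, the
#'   `pretrained` embedding (if any), a per-epoch `history` tibble
#'   (`epoch`, `loss`, `val_auc`) and `best_epoch`.
#' @export
fit_bigru <- function(data, config = train_config(), pretrained = NULL,
                      verbose = FALSE) {
  stopifnot(inherits(config, "train_config"))
  validate_dataset(data)
  if (!"split" %in% names(data)) {
    data <- split_dataset(data, seed = derive_seed(config$seed, "split"))
  }
  validate_dataset(data, require_split = TRUE)
  train <- data[data$split == "train", , drop = FALSE]
  val <- data[data$split == "validation", , drop = FALSE]
  if (nrow(train) == 0 || nrow(val) == 0) {
    abort("fit_bigru: training and validation splits must be non-empty")
  }

  vocab <- kmer_vocab(config$k)
  if (config$embedding_strategy != "no_init" && is.null(pretrained)) {
    corpus <- build_corpus(train, k = config$k, s = config$s)
    pretrained <- train_kmer_embedding(
      corpus, vocab = vocab, d = config$d,
      seed = derive_seed(config$seed, "embedding")
    )
  }
  if (!is.null(pretrained) &&
      (pretrained$d != config$d || pretrained$vocab$k != config$k)) {
    abort("pretrained embedding does not match config k/d")
  }
  emb <- embedding_layer(config$embedding_strategy, pretrained = pretrained,
                         V = vocab_size(vocab), d = config$d,
                         seed = derive_seed(config$seed, "emb_init"))
  model <- bigru_model(
    vocab, emb, units = config$units, merge_mode = config$merge_mode,
    head_input = config$head_input, n_layers = config$n_layers,
    seed = derive_seed(config$seed, "weights")
  )

  enc_train <- encode_dataset(train, config$k, config$s, vocab)
  enc_val <- encode_dataset(val, config$k, config$s, vocab)
  y_train <- train$label
  y_val <- val$label

  opt <- make_optimizer(config$optimizer, config$learning_rate)
  params <- model_flat_params(model)
  n <- nrow(enc_train$idx)
  best <- list(val_auc = -Inf, params = params, epoch = 0L)
  history <- vector("list", config$epochs)
  stale <- 0L

  for (epoch in seq_len(config$epochs)) {
    ord <- with_seed(derive_seed(config$seed, paste0("batches", epoch)),
                     sample.int(n))
    batch_starts <- seq.int(1L, n, by = config$batch_size)
    epoch_loss <- 0
    for (b in batch_starts) {
      rows <- ord[b:min(b + config$batch_size - 1L, n)]
      model <- model_set_flat(model, params)
      fw <- forward_model(model, enc_train$idx[rows, , drop = FALSE],
                          enc_train$mask[rows, , drop = FALSE],
                          keep_cache = TRUE)
      loss_b <- bce_loss(fw$p, y_train[rows])
      if (!is.finite(loss_b)) {
        abort(paste0("training diverged (non-finite loss) at epoch ", epoch))
      }
      epoch_loss <- epoch_loss + loss_b
      dlogit <- (fw$p - y_train[rows]) / length(rows)
      grads <- backward_model(model, fw, dlogit)
      params <- opt$step(params, grads)
    }
    model <- model_set_flat(model, params)
    p_val <- forward_model(model, enc_val$idx, enc_val$mask)$p
    val_auc <- auc_score(p_val, y_val)
    mean_loss <- epoch_loss / n
    history[[epoch]] <- tibble::tibble(epoch = epoch, loss = mean_loss,
                                       val_auc = val_auc)
    if (verbose) {
      message(sprintf("epoch %d  loss %.4f  val_auc %.4f", epoch, mean_loss,
                      val_auc))
    }
    if (val_auc > best$val_auc) {
      best <- list(val_auc = val_auc, params = params, epoch = epoch)
      stale <- 0L
    } else {
      stale <- stale + 1L
      if (stale >= config$patience) break
    }
  }
  model <- model_set_flat(model, best$params)
  structure(
    list(
      model = model, config = config, pretrained = pretrained,
      history = dplyr::bind_rows(history), best_epoch = best$epoch,
      val_auc = best$val_auc
    ),
    class = "bigru_fit"
  )
}

#' @export
print.bigru_fit <- function(x, ...) {
  cat("<bigru_fit> epochs run =", nrow(x$history),
      " best epoch =", x$best_epoch,
      sprintf(" val AUC = %.4f", x$val_auc), "\n")
  print(x$config)
  invisible(x)
}
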