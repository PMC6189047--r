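#' Write a model checkpoint
#'
#' Serialises a fitted classifier as a two-file pair: `<prefix>.json`, a
#' sidecar with the architecture and provenance (units, merge mode, k, s,
#' d, embedding strategy, vocabulary descriptor, seed), and
#' `<prefix>_weights.json` holding every weight array at full double
#' precision, sufficient to reload and reproduce predictions bit-for-bit
#' on the same platform.
#'
#' @param fit A `bigru_fit`.
#' @param prefix Output path prefix.
#' @return The files written, invisibly.
#' @export
write_checkpoint <- function(fit, prefix) {
  stopifnot(inherits(fit, "bigru_fit"))
  model <- fit$model
  sidecar <- list(
    package_version = as.character(utils::packageVersion("kmergru")),
    units = model$units, merge_mode = model$merge_mode,
    head_input = model$head_input, n_layers = model$n_layers,
    k = fit$config$k, s = fit$config$s, d = model$d,
    embedding_strategy = model$embedding$strategy,
    embedding_trainable = model$embedding$trainable,
    optimizer = fit$config$optimizer, seed = fit$config$seed,
    best_epoch = fit$best_epoch, val_auc = fit$val_auc,
    vocab = list(k = model$vocab$k, mode = model$vocab$mode,
                 V = vocab_size(model$vocab),
                 tokens = model$vocab$tokens)
  )
  sf <- paste0(prefix, ".json")
  jsonlite::write_json(sidecar, sf, auto_unbox = TRUE, digits = NA)
  weights <- model_flat_params(model)
  if (!model$embedding$trainable) weights$emb <- model$embedding$weights
  wf <- paste0(prefix, "_weights.json")
  # C99 hex-float strings: plain text, yet the doubles round-trip exactly
  ser <- lapply(weights, function(w) {
    list(dim = dim(as.matrix(w)), data = sprintf("%a", as.vector(w)))
  })
  jsonlite::write_json(ser, wf)
  invisible(c(sf, wf))
}

#' Read a model checkpoint written by [write_checkpoint()]
#'
#' @param prefix Path prefix.
#' @return A `bigru_fit` with the reloaded model (history is not stored in
#'   a checkpoint and comes back empty).
#' @export
read_checkpoint <- function(prefix) {
  sc <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  ser <- jsonlite::read_json(paste0(prefix, "_weights.json"),
                             simplifyVector = TRUE)
  weights <- lapply(ser, function(w) {
    m <- matrix(as.numeric(w$data), nrow = w$dim[1], ncol = w$dim[2])
    m
  })
  vocab <- structure(
    list(k = sc$vocab$k, mode = sc$vocab$mode, tokens = sc$vocab$tokens,
         index = setNames(seq_along(sc$vocab$tokens), sc$vocab$tokens)),
    class = "kmer_vocab"
  )
  emb <- list(weights = weights$emb, trainable = sc$embedding_trainable,
              strategy = sc$embedding_strategy)
  model <- bigru_model(vocab, emb, units = sc$units,
                       merge_mode = sc$merge_mode, head_input = sc$head_input,
                       n_layers = sc$n_layers, seed = sc$seed)
  flat <- weights
  flat$beta <- drop(weights$beta)
  flat$bias <- drop(weights$bias)
  for (nm in names(flat)) {
    if (grepl("_b_[zrh]$", nm)) flat[[nm]] <- drop(flat[[nm]])
  }
  model <- model_set_flat(model, flat)
  model$embedding$weights <- weights$emb
  cfg <- train_config(
    units = sc$units, optimizer = sc$optimizer,
    embedding_strategy = sc$embedding_strategy,
    k = sc$k, s = sc$s, d = sc$d, merge_mode = sc$merge_mode,
    head_input = sc$head_input, n_layers = sc$n_layers, seed = sc$seed
  )
  structure(
    list(model = model, config = cfg, pretrained = NULL,
         history = tibble::tibble(epoch = integer(), loss = numeric(),
                                  val_auc = numeric()),
         best_epoch = sc$best_epoch, val_auc = sc$val_auc),
    class = "bigru_fit"
  )
}
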