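#' Construct an (untrained) bidirectional GRU sequence classifier
#'
#' The network is: embedding lookup, one or more bidirectional GRU layers,
#' a merge of the two directions' states, and a dense + logistic-sigmoid
#' head giving the probability that the sequence is a binding region.
#' By default the head consumes the final hidden state of each direction;
#' `head_input = "mean_pool"` averages the states over unmasked steps
#' instead.
#'
#' @param vocab A `kmer_vocab` describing the k-mer index space.
#' @param embedding An embedding layer from [embedding_layer()], or a
#'   `kmer_embedding` (used as an `init_train` layer).
#' @param units GRU hidden size per direction (grid values 50, 80, 100).
#' @param merge_mode How the two directions are merged: `"concatenate"`
#'   (default), `"sum"`, `"average"` or `"multiplication"`.
#' @param head_input `"final"` (default) or `"mean_pool"`.
#' @param n_layers Number of stacked bidirectional layers (default 1).
#' @param seed Seed for weight initialisation.
#' @return A `bigru_model` object.
#' @export
bigru_model <- function(vocab, embedding, units = 50L,
                        merge_mode = c("concatenate", "sum", "average",
                                       "multiplication"),
                        head_input = c("final", "mean_pool"),
                        n_layers = 1L, seed = 1L) {
  merge_mode <- match.arg(merge_mode)
  head_input <- match.arg(head_input)
  stopifnot(inherits(vocab, "kmer_vocab"), n_layers >= 1)
  if (inherits(embedding, "kmer_embedding")) {
    embedding <- embedding_layer("init_train", pretrained = embedding)
  }
  d <- ncol(embedding$weights)
  if (nrow(embedding$weights) != vocab_size(vocab) + 1) {
    abort("embedding rows must equal vocabulary size + 1 (padding row)")
  }
  units <- as.integer(units)
  layers <- vector("list", n_layers)
  for (l in seq_len(n_layers)) {
    din <- if (l == 1) d else 2L * units
    layers[[l]] <- list(
      fwd = gru_params(units, din, seed = derive_seed(seed, paste0("fwd", l))),
      bwd = gru_params(units, din, seed = derive_seed(seed, paste0("bwd", l)))
    )
  }
  merged_dim <- if (merge_mode == "concatenate") 2L * units else units
  head <- with_seed(derive_seed(seed, "head"), {
    lim <- sqrt(6 / (merged_dim + 1))
    list(beta = runif(merged_dim, -lim, lim), bias = 0)
  })
  structure(
    list(
      vocab = vocab, embedding = embedding, layers = layers, units = units,
      d = d, merge_mode = merge_mode, head_input = head_input,
      n_layers = as.integer(n_layers), head = head, seed = seed
    ),
    class = "bigru_model"
  )
}

#' @export
print.bigru_model <- function(x, ...) {
  cat("<bigru_model> units =", x$units, " layers =", x$n_layers,
      " merge =", x$merge_mode,
      " d =", x$d, " V =", vocab_size(x$vocab),
      " embedding =", x$embedding$strategy, "\n")
  invisible(x)
}

# Full forward pass over a batch. idx: B x T integer index matrix (0 =
# padding/OOV); mask: B x T 0/1 matrix marking real steps. Padding-index
# steps still count as real steps (zero input vector) unless masked.
forward_model <- function(model, idx, mask = NULL, keep_cache = FALSE) {
  B <- nrow(idx); Tn <- ncol(idx)
  if (is.null(mask)) mask <- matrix(1, B, Tn)
  storage.mode(mask) <- "double"
  if (any(rowSums(mask) == 0)) abort("forward_model: all-masked input row")
  E <- model$embedding$weights
  Xseq <- lapply(seq_len(Tn), function(t) E[idx[, t] + 1L, , drop = FALSE])
  rmask <- mask[, rev(seq_len(Tn)), drop = FALSE]
  lens <- rowSums(mask)

  layer_caches <- vector("list", model$n_layers)
  for (l in seq_len(model$n_layers)) {
    rXseq <- Xseq[rev(seq_len(Tn))]
    fwd <- gru_dir_forward(model$layers[[l]]$fwd, Xseq, mask, keep_cache)
    bwd <- gru_dir_forward(model$layers[[l]]$bwd, rXseq, rmask, keep_cache)
    layer_caches[[l]] <- list(Xseq = Xseq, fwd = fwd, bwd = bwd)
    if (l < model$n_layers) {
      Xseq <- lapply(seq_len(Tn), function(t) {
        cbind(fwd$states[[t]], bwd$states[[Tn + 1L - t]])
      })
    }
  }
  fwd <- layer_caches[[model$n_layers]]$fwd
  bwd <- layer_caches[[model$n_layers]]$bwd
  if (model$head_input == "final") {
    fout <- fwd$h_final
    bout <- bwd$h_final
  } else {
    pool <- function(run, mk) {
      acc <- matrix(0, B, model$units)
      for (t in seq_len(Tn)) acc <- acc + mk[, t] * run$states[[t]]
      acc / lens
    }
    fout <- pool(fwd, mask)
    bout <- pool(bwd, rmask)
  }
  merged <- merge_states(fout, bout, model$merge_mode)
  logits <- drop(merged %*% model$head$beta) + model$head$bias
  p <- sigmoid(logits)
  out <- list(p = p, logits = logits, merged = merged)
  if (keep_cache) {
    out$cache <- list(layers = layer_caches, mask = mask, rmask = rmask,
                      lens = lens, fout = fout, bout = bout, idx = idx,
                      Tn = Tn, B = B)
  }
  out
}

# Backward pass given d loss / d logits (length B). Returns a flat named
# gradient list aligned with model_flat_params().
backward_model <- function(model, fw, dlogit) {
  cc <- fw$cache
  Tn <- cc$Tn; B <- cc$B
  units <- model$units
  grads <- list(
    beta = drop(crossprod(fw$merged, dlogit)),
    bias = sum(dlogit)
  )
  dmerged <- outer(dlogit, model$head$beta)
  mb <- merge_backward(dmerged, cc$fout, cc$bout, model$merge_mode, units)

  null_states <- vector("list", Tn)
  if (model$head_input == "final") {
    d_top <- list(f_final = mb$df, b_final = mb$db,
                  f_states = null_states, b_states = null_states)
  } else {
    zero <- matrix(0, B, units)
    f_states <- lapply(seq_len(Tn), function(t) mb$df * (cc$mask[, t] / cc$lens))
    b_states <- lapply(seq_len(Tn), function(t) mb$db * (cc$rmask[, t] / cc$lens))
    d_top <- list(f_final = zero, b_final = zero,
                  f_states = f_states, b_states = b_states)
  }

  d_next <- d_top
  for (l in rev(seq_len(model$n_layers))) {
    lc <- cc$layers[[l]]
    rXseq <- lc$Xseq[rev(seq_len(Tn))]
    bf <- gru_dir_backward(model$layers[[l]]$fwd, lc$Xseq, lc$fwd,
                           d_next$f_states, d_next$f_final)
    bb <- gru_dir_backward(model$layers[[l]]$bwd, rXseq, lc$bwd,
                           d_next$b_states, d_next$b_final)
    for (nm in names(bf$grads)) {
      grads[[paste0("L", l, "_fwd_", nm)]] <- bf$grads[[nm]]
      grads[[paste0("L", l, "_bwd_", nm)]] <- bb$grads[[nm]]
    }
    dXseq <- lapply(seq_len(Tn), function(t) {
      bf$dX[[t]] + bb$dX[[Tn + 1L - t]]
    })
    if (l > 1) {
      zero <- matrix(0, B, units)
      d_next <- list(
        f_final = zero, b_final = zero,
        f_states = lapply(dXseq, function(m) m[, seq_len(units), drop = FALSE]),
        b_states = lapply(seq_len(Tn), function(t) {
          dXseq[[Tn + 1L - t]][, units + seq_len(units), drop = FALSE]
        })
      )
    } else if (model$embedding$trainable) {
      all_idx <- as.vector(cc$idx) + 1L
      dX_all <- do.call(rbind, dXseq)
      agg <- rowsum(dX_all, group = all_idx)
      dE <- matrix(0, nrow(model$embedding$weights), model$d)
      dE[as.integer(rownames(agg)), ] <- agg
      dE[1, ] <- 0  # padding row stays fixed at zero
      grads$emb <- dE
    }
  }
  grads
}

model_flat_params <- function(model) {
  out <- list(beta = model$head$beta, bias = model$head$bias)
  for (l in seq_len(model$n_layers)) {
    for (dir in c("fwd", "bwd")) {
      p <- model$layers[[l]][[dir]]
      for (nm in names(p)) out[[paste0("L", l, "_", dir, "_", nm)]] <- p[[nm]]
    }
  }
  if (model$embedding$trainable) out$emb <- model$embedding$weights
  out
}

model_set_flat <- function(model, flat) {
  model$head$beta <- flat$beta
  model$head$bias <- flat$bias
  for (l in seq_len(model$n_layers)) {
    for (dir in c("fwd", "bwd")) {
      for (nm in names(model$layers[[l]][[dir]])) {
        model$layers[[l]][[dir]][[nm]] <- flat[[paste0("L", l, "_", dir, "_", nm)]]
      }
    }
  }
  if (model$embedding$trainable && !is.null(flat$emb)) {
    model$embedding$weights <- flat$emb
  }
  model
}

#' Run the bidirectional GRU over one embedded sequence
#'
#' The forward layer consumes steps `1..N` in order and the backward layer
#' consumes `N..1`; both start from a zero state. Masked (padding) steps
#' never update the hidden state, so appending padding leaves the output
#' unchanged. The two directions' final states over unmasked steps are
#' merged per the model's merge mode.
#'
#' @param embedded A numeric `N x d` matrix of embedded k-mer vectors.
#' @param mask Logical (or 0/1) vector of length `N`; `TRUE` marks real
#'   steps. Default all `TRUE`.
#' @param model A `bigru_model`.
#' @return The merged state vector (length `2 * units` for concatenate,
#'   `units` otherwise).
#' @export
run_bigru <- function(embedded, mask = NULL, model) {
  stopifnot(inherits(model, "bigru_model"), is.matrix(embedded))
  Tn <- nrow(embedded)
  if (Tn < 1) abort("run_bigru: empty input")
  if (is.null(mask)) mask <- rep(TRUE, Tn)
  if (!any(mask)) abort("run_bigru: all steps are masked")
  mk <- matrix(as.numeric(mask), 1, Tn)
  Xseq <- lapply(seq_len(Tn), function(t) embedded[t, , drop = FALSE])
  fwd <- gru_dir_forward(model$layers[[1]]$fwd, Xseq, mk)
  bwd <- gru_dir_forward(model$layers[[1]]$bwd, Xseq[rev(seq_len(Tn))],
                         mk[, rev(seq_len(Tn)), drop = FALSE])
  if (model$n_layers > 1) {
    for (l in 2:model$n_layers) {
      Xseq <- lapply(seq_len(Tn), function(t) {
        cbind(fwd$states[[t]], bwd$states[[Tn + 1L - t]])
      })
      fwd <- gru_dir_forward(model$layers[[l]]$fwd, Xseq, mk)
      bwd <- gru_dir_forward(model$layers[[l]]$bwd, Xseq[rev(seq_len(Tn))],
                             mk[, rev(seq_len(Tn)), drop = FALSE])
    }
  }
  drop(merge_states(fwd$h_final, bwd$h_final, model$merge_mode))
}

#' Predict binding probabilities for encoded k-mer sequences
#'
#' Composes embedding lookup, the bidirectional GRU and the dense +
#' sigmoid head.
#'
#' @param kmer_indices An integer vector of k-mer indices, a list of such
#'   vectors, or a `B x T` integer matrix.
#' @param model A `bigru_model`.
#' @return Numeric vector of probabilities in (0, 1), one per sequence.
#' @export
predict_proba <- function(kmer_indices, model) {
  stopifnot(inherits(model, "bigru_model"))
  enc <- encode_batch(kmer_indices, vocab_size(model$vocab))
  forward_model(model, enc$idx, enc$mask)$p
}

# Pad a list/vector of index sequences to a B x T matrix + mask.
encode_batch <- function(kmer_indices, V) {
  if (is.matrix(kmer_indices)) {
    if (any(kmer_indices < 0 | kmer_indices > V)) abort("index out of range")
    return(list(idx = kmer_indices,
                mask = matrix(1, nrow(kmer_indices), ncol(kmer_indices))))
  }
  if (!is.list(kmer_indices)) kmer_indices <- list(kmer_indices)
  if (any(unlist(kmer_indices) < 0 | unlist(kmer_indices) > V)) {
    abort("index out of range")
  }
  lens <- lengths(kmer_indices)
  if (any(lens == 0)) abort("empty index sequence")
  Tn <- max(lens)
  B <- length(kmer_indices)
  idx <- matrix(0L, B, Tn)
  mask <- matrix(0, B, Tn)
  for (i in seq_len(B)) {
    idx[i, seq_len(lens[i])] <- kmer_indices[[i]]
    mask[i, seq_len(lens[i])] <- 1
  }
  list(idx = idx, mask = mask)
}

#' Predict on a dataset tibble
#'
#' Tokenizes and encodes each sequence with the model's `k`, `s` and
#' vocabulary, then scores it.
#'
#' @param object A fitted `bigru_fit` (see [fit_bigru()]).
#' @param data A tibble with `id` and `sequence` columns.
#' @param ... Unused.
#' @return `data` with an added `.pred` column of probabilities.
#' @export
predict.bigru_fit <- function(object, data, ...) {
  stopifnot("sequence" %in% names(data))
  enc <- encode_dataset(data, object$config$k, object$config$s,
                        object$model$vocab)
  p <- forward_model(object$model, enc$idx, enc$mask)$p
  data$.pred <- p
  data
}

# Tokenize + encode a dataset into a padded index matrix.
encode_dataset <- function(data, k, s, vocab) {
  seqs <- lapply(data$sequence, split_kmers, k = k, s = s)
  codes <- lapply(seqs, encode_kmers, vocab = vocab)
  encode_batch(lapply(codes, as.integer), vocab_size(vocab))
}

#' Bernoulli negative log-likelihood loss
#'
#' `-sum(y * log(p) + (1 - y) * log(1 - p))`, with probabilities clipped
#' to `[eps, 1 - eps]` before the logarithms.
#'
#' @param p Predicted probabilities in (0, 1).
#' @param y Binary labels (0/1).
#' @param eps Clipping constant (default `1e-7`).
#' @return A non-negative scalar.
#' @examples
#' bce_loss(0.5, 1)               # log(2)
#' bce_loss(c(0.9, 0.1), c(1, 0)) # -2 * log(0.9)
#' @export
bce_loss <- function(p, y, eps = 1e-7) {
  if (length(p) != length(y)) abort("bce_loss: length mismatch")
  if (!all(y %in% c(0, 1))) abort("bce_loss: labels must be 0 or 1")
  p <- pmin(pmax(p, eps), 1 - eps)
  -sum(y * log(p) + (1 - y) * log(1 - p))
}
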