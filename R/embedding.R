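#' Build a k-mer corpus from labelled datasets
#'
#' Produces one k-mer "sentence" per input sequence, preserving record
#' order, for use as a word2vec-style training corpus.
#'
#' @param data A labelled dataset tibble, or a list of them.
#' @param k,s K-mer length and stride.
#' @return A list of character vectors, one per input record.
#' @export
build_corpus <- function(data, k = 5L, s = 2L) {
  if (is.data.frame(data)) data <- list(data)
  if (length(data) == 0) abort("build_corpus: empty dataset list")
  data <- dplyr::bind_rows(lapply(data, function(d) d[, "sequence", drop = FALSE]))
  lapply(data$sequence, split_kmers, k = k, s = s)
}

#' Train k-mer embedding vectors from a corpus
#'
#' Learns a dense vector for every k-mer in the vocabulary from
#' co-occurrence in the corpus, using a word2vec-style trainer (CBOW or
#' skip-gram with negative sampling) run single-threaded so a fixed seed
#' reproduces the matrix exactly. Every in-vocabulary k-mer receives a
#' vector regardless of its corpus frequency (there is no minimum count),
#' so no OOV holes appear at prediction time.
#'
#' @param corpus A list of character vectors of k-mer tokens
#'   ([build_corpus()]).
#' @param vocab A `kmer_vocab`; defaults to the full `4^k` vocabulary of
#'   the corpus's k.
#' @param d Embedding dimension (default 50).
#' @param window Maximum context window (default 5); the effective window
#'   for each centre is drawn uniformly from `1..window`.
#' @param epochs Training passes over the corpus (default 5).
#' @param algorithm `"cbow"` (default) or `"skipgram"`.
#' @param negative Number of negative samples per target (default 5).
#' @param learning_rate Initial learning rate; decays linearly. Defaults to
#'   0.05 for CBOW and 0.025 for skip-gram.
#' @param seed Integer seed.
#' @return A `kmer_embedding` object: `matrix` of shape `(V + 1) x d` whose
#'   first row (index 0, padding/OOV) is all zeros, the `vocab`, and a
#'   `provenance` list recording all hyper-parameters.
#' @export
train_kmer_embedding <- function(corpus, vocab = NULL, d = 50L, window = 5L,
                                 epochs = 5L, algorithm = c("cbow", "skipgram"),
                                 negative = 5L, learning_rate = NULL,
                                 seed = 1L) {
  algorithm <- match.arg(algorithm)
  if (length(corpus) == 0) abort("train_kmer_embedding: empty corpus")
  d <- as.integer(d)
  if (d < 1) abort("embedding dimension d must be >= 1")
  if (is.null(vocab)) {
    k <- nchar(corpus[[1]][1])
    vocab <- kmer_vocab(k)
  }
  if (is.null(learning_rate)) {
    learning_rate <- if (algorithm == "cbow") 0.05 else 0.025
  }
  sentences <- lapply(corpus, function(x) encode_kmers(x, vocab))
  if (all(lengths(sentences) < 2)) {
    warn("every sentence is shorter than 2 tokens; embedding sees no context pairs")
  }
  V <- vocab_size(vocab)
  W <- cpp_train_word2vec(
    sentences = lapply(sentences, as.integer),
    V = as.integer(V), d = d, window = as.integer(window),
    epochs = as.integer(epochs), negative = as.integer(negative),
    alpha = learning_rate, cbow = algorithm == "cbow",
    seed = as.integer(seed)
  )
  mat <- rbind(numeric(d), W)  # row 1 = index 0 (padding/OOV), all zeros
  rownames(mat) <- c("<pad>", vocab$tokens)
  structure(
    list(
      matrix = mat, d = d, vocab = vocab,
      provenance = list(
        source = "pretrained", algorithm = algorithm, window = window,
        epochs = epochs, negative = negative,
        learning_rate = learning_rate, seed = seed,
        n_sentences = length(sentences)
      )
    ),
    class = "kmer_embedding"
  )
}

#' @export
print.kmer_embedding <- function(x, ...) {
  cat("<kmer_embedding> V =", vocab_size(x$vocab), " d =", x$d,
      " source =", x$provenance$source, "\n")
  invisible(x)
}

#' Look up embedding vectors for a sequence of k-mer indices
#'
#' @param indices Integer vector of k-mer indices in `0..V`; index 0
#'   (padding/OOV) yields the zero vector.
#' @param embedding A `kmer_embedding`, or a bare `(V + 1) x d` matrix.
#' @return A numeric matrix of shape `length(indices) x d`.
#' @export
embedding_lookup <- function(indices, embedding) {
  mat <- if (inherits(embedding, "kmer_embedding")) embedding$matrix else embedding
  if (any(indices < 0 | indices > nrow(mat) - 1)) {
    abort("embedding_lookup: index out of range")
  }
  out <- mat[indices + 1L, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Initialise an embedding layer under one of three strategies
#'
#' * `no_init`: weights drawn i.i.d. uniform on `[-0.05, 0.05]` (seeded);
#'   trainable.
#' * `init_no_train`: weights equal the pretrained matrix exactly; frozen.
#' * `init_train`: weights equal the pretrained matrix exactly; fine-tuned
#'   during training.
#'
#' @param strategy One of `"no_init"`, `"init_no_train"`, `"init_train"`.
#' @param pretrained A `kmer_embedding` (required for the `init_*`
#'   strategies).
#' @param V Vocabulary size (required for `no_init` without `pretrained`).
#' @param d Embedding dimension (idem).
#' @param seed Seed for the random initialisation.
#' @return A list with elements `weights` (`(V + 1) x d`, row 1 zero),
#'   `trainable` (logical) and `strategy`.
#' @export
embedding_layer <- function(strategy = c("init_train", "no_init", "init_no_train"),
                            pretrained = NULL, V = NULL, d = NULL, seed = 1L) {
  strategy <- match.arg(strategy)
  if (strategy %in% c("init_no_train", "init_train")) {
    if (!inherits(pretrained, "kmer_embedding")) {
      abort(paste0("strategy '", strategy, "' requires a pretrained kmer_embedding"))
    }
    if (!is.null(V) && V != vocab_size(pretrained$vocab)) {
      abort("pretrained vocabulary size does not match V")
    }
    if (!is.null(d) && d != pretrained$d) {
      abort("pretrained embedding dimension does not match d")
    }
    weights <- pretrained$matrix
  } else {
    if (!is.null(pretrained)) {
      V <- V %||% vocab_size(pretrained$vocab)
      d <- d %||% pretrained$d
    }
    if (is.null(V) || is.null(d)) abort("no_init requires V and d")
    weights <- with_seed(seed, {
      matrix(runif((V + 1) * d, -0.05, 0.05), nrow = V + 1, ncol = d)
    })
    weights[1, ] <- 0
  }
  list(
    weights = unname(weights),
    trainable = strategy != "init_no_train",
    strategy = strategy
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write an embedding to disk
#'
#' Writes a two-file pair: `<prefix>.json` (header: k, d, V, algorithm,
#' window, epochs, seed, vocabulary mode; and a note that the matrix is
#' stored tokens-as-rows) and `<prefix>.vec` in word2vec text format
#' (`token v1 ... vd` per line; the padding row is not written).
#'
#' @param embedding A `kmer_embedding`.
#' @param prefix Output path prefix.
#' @return The files written, invisibly.
#' @export
write_embedding <- function(embedding, prefix) {
  stopifnot(inherits(embedding, "kmer_embedding"))
  header <- list(
    k = embedding$vocab$k, d = embedding$d, V = vocab_size(embedding$vocab),
    vocab_mode = embedding$vocab$mode,
    orientation = "tokens_as_rows",
    provenance = embedding$provenance
  )
  hf <- paste0(prefix, ".json")
  jsonlite::write_json(header, hf, auto_unbox = TRUE, digits = NA)
  vf <- paste0(prefix, ".vec")
  mat <- embedding$matrix[-1, , drop = FALSE]
  lines <- c(
    paste(nrow(mat), ncol(mat)),
    vapply(seq_len(nrow(mat)), function(i) {
      paste(c(rownames(mat)[i], format(mat[i, ], digits = 17, trim = TRUE,
                                       scientific = TRUE)), collapse = " ")
    }, character(1))
  )
  writeLines(lines, vf)
  invisible(c(hf, vf))
}

#' Read an embedding written by [write_embedding()]
#'
#' @param prefix Path prefix.
#' @return A `kmer_embedding`.
#' @export
read_embedding <- function(prefix) {
  header <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  lines <- readLines(paste0(prefix, ".vec"))
  dims <- as.integer(strsplit(lines[1], " ")[[1]])
  body <- strsplit(lines[-1], " ", fixed = TRUE)
  tokens <- vapply(body, `[[`, character(1), 1)
  mat <- t(vapply(body, function(x) as.numeric(x[-1]), numeric(dims[2])))
  vocab <- structure(
    list(k = header$k, mode = header$vocab_mode, tokens = tokens,
         index = setNames(seq_along(tokens), tokens)),
    class = "kmer_vocab"
  )
  full <- rbind(numeric(dims[2]), mat)
  rownames(full) <- c("<pad>", tokens)
  structure(
    list(matrix = full, d = header$d, vocab = vocab,
         provenance = header$provenance),
    class = "kmer_embedding"
  )
}
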