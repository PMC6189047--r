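#' Split a DNA sequence into overlapping k-mers
#'
#' Slides a window of length `k` along the sequence with stride `s`. The
#' number of tokens is `floor((L - k) / s) + 1` where `L` is the sequence
#' length; trailing bases that cannot fill a window are dropped. Window `t`
#' (0-based) covers the half-open interval `[t*s, t*s + k)`.
#'
#' @param sequence A single DNA string over `A,C,G,T,N`.
#' @param k K-mer length, `1 <= k <= nchar(sequence)`.
#' @param s Stride between window starts, `s >= 1`.
#' @return A character vector of k-mer tokens.
#' @examples
#' split_kmers("ACGTACGTA", k = 5, s = 2)
#' length(split_kmers(strrep("A", 101), k = 5, s = 2))  # 49
#' @export
split_kmers <- function(sequence, k, s) {
  stopifnot(length(sequence) == 1, is.character(sequence))
  k <- as.integer(k)
  s <- as.integer(s)
  L <- nchar(sequence)
  if (s < 1) abort("stride s must be >= 1")
  if (k < 1) abort("k must be >= 1")
  if (k > L) {
    abort(paste0("k (", k, ") exceeds sequence length (", L, "): no window fits"))
  }
  bad <- regexpr("[^ACGTN]", sequence)
  if (bad > 0) {
    abort(paste0("non-ACGTN character '", substr(sequence, bad, bad),
                 "' at position ", bad))
  }
  starts <- seq.int(1L, L - k + 1L, by = s)
  substring(sequence, starts, starts + k - 1L)
}

#' Expected k-mer token count for a sequence length
#'
#' @param L Sequence length(s).
#' @param k K-mer length.
#' @param s Stride.
#' @return `floor((L - k) / s) + 1`, the number of windows that fit.
#' @export
n_kmers <- function(L, k, s) {
  as.integer(floor((L - k) / s) + 1)
}

#' Build a k-mer vocabulary
#'
#' Maps k-mer strings over `A,C,G,T` to positive integer indices `1..V`.
#' Index 0 is reserved for padding and out-of-vocabulary tokens and is
#' never assigned. Mode `"full"` enumerates all `4^k` k-mers in
#' lexicographic order; mode `"observed"` indexes only k-mers seen in
#' `corpus`, ordered by descending frequency then lexicographically.
#'
#' @param k K-mer length, `k >= 1`.
#' @param mode `"full"` (default, recommended for `k <= 8`) or
#'   `"observed"`.
#' @param corpus For `mode = "observed"`: a list of character vectors of
#'   k-mer tokens (as produced by [split_kmers()] / [build_corpus()]).
#' @return A `kmer_vocab` object.
#' @examples
#' v <- kmer_vocab(1)
#' v$tokens  # A C G T -> indices 1..4
#' @export
kmer_vocab <- function(k, mode = c("full", "observed"), corpus = NULL) {
  mode <- match.arg(mode)
  k <- as.integer(k)
  if (k < 1) abort("k must be >= 1")
  if (mode == "full") {
    if (k > 10) abort("full vocabulary with k > 10 is too large; use mode = 'observed'")
    tokens <- do.call(paste0, expand.grid(
      rep(list(c("A", "C", "G", "T")), k),
      stringsAsFactors = FALSE
    )[, k:1, drop = FALSE])
    tokens <- sort(tokens)
  } else {
    if (is.null(corpus)) abort("mode = 'observed' requires a corpus")
    all_tokens <- unlist(corpus, use.names = FALSE)
    all_tokens <- all_tokens[grepl("^[ACGT]+$", all_tokens)]
    if (length(all_tokens) == 0) abort("corpus contains no ACGT-only k-mers")
    if (any(nchar(all_tokens) != k)) abort("corpus tokens must all have length k")
    tab <- table(all_tokens)
    tokens <- names(tab)[order(-as.vector(tab), names(tab))]
  }
  structure(
    list(k = k, mode = mode, tokens = tokens,
         index = setNames(seq_along(tokens), tokens)),
    class = "kmer_vocab"
  )
}

#' @export
print.kmer_vocab <- function(x, ...) {
  cat("<kmer_vocab> k =", x$k, " mode =", x$mode, " V =", length(x$tokens), "\n")
  invisible(x)
}

#' Vocabulary size
#' @param vocab A `kmer_vocab`.
#' @return Integer number of indexed k-mers (excluding the reserved 0).
#' @export
vocab_size <- function(vocab) length(vocab$tokens)

#' Encode k-mer tokens as integer indices
#'
#' Out-of-vocabulary tokens (including any window containing a non-ACGT
#' base such as `N`) map to the reserved index 0; their count is attached
#' as the `oov` attribute.
#'
#' @param tokens Character vector of k-mers.
#' @param vocab A `kmer_vocab` with matching `k`.
#' @return Integer vector of indices in `0..V`, with attribute `oov`.
#' @export
encode_kmers <- function(tokens, vocab) {
  stopifnot(inherits(vocab, "kmer_vocab"))
  if (length(tokens) > 0 && any(nchar(tokens) != vocab$k)) {
    abort(paste0("token length does not match vocabulary k = ", vocab$k))
  }
  idx <- unname(vocab$index[tokens])
  idx[is.na(idx)] <- 0L
  structure(as.integer(idx), oov = sum(idx == 0L))
}

#' Decode integer indices back to k-mer tokens
#'
#' @param indices Integer vector in `0..V`; 0 decodes to `NA`.
#' @param vocab A `kmer_vocab`.
#' @return Character vector of tokens.
#' @export
decode_kmers <- function(indices, vocab) {
  stopifnot(inherits(vocab, "kmer_vocab"))
  if (any(indices < 0 | indices > vocab_size(vocab))) {
    abort("index out of range for vocabulary")
  }
  out <- rep(NA_character_, length(indices))
  out[indices > 0] <- vocab$tokens[indices[indices > 0]]
  out
}

#' Tokenize every sequence in a dataset
#'
#' Adds a list-column `tokens` holding each record's k-mer tokens.
#'
#' @param data A tibble with a `sequence` column.
#' @param k,s K-mer length and stride.
#' @return `data` with an added list-column `tokens`.
#' @export
tokenize <- function(data, k = 5L, s = 2L) {
  stopifnot("sequence" %in% names(data))
  data$tokens <- lapply(data$sequence, split_kmers, k = k, s = s)
  data
}
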