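#' Define a motif as a position weight matrix
#'
#' Each row of the PWM gives the probability of A, C, G, T at one motif
#' position. Convenience: a consensus string plus a per-position consensus
#' probability builds the PWM directly (the remaining mass is spread
#' evenly over the other three bases).
#'
#' @param consensus A consensus string over `A,C,G,T`, or `NULL` when
#'   `pwm` is given.
#' @param prob Probability of the consensus base at each position
#'   (default 1: a point-mass, maximally informative motif).
#' @param pwm Optional `W x 4` probability matrix (columns A, C, G, T;
#'   rows summing to 1) used instead of `consensus`.
#' @param name Motif name.
#' @return A `motif_model` with fields `pwm`, `consensus`, `ic`
#'   (information content per column, bits) and `name`.
#' @examples
#' motif_model("TGACTCAG")
#' @export
motif_model <- function(consensus = NULL, prob = 1, pwm = NULL,
                        name = "motif") {
  bases <- c("A", "C", "G", "T")
  if (is.null(pwm)) {
    if (is.null(consensus) || !grepl("^[ACGT]+$", consensus)) {
      abort("motif_model: consensus must be a non-empty ACGT string")
    }
    cons <- strsplit(consensus, "")[[1]]
    pwm <- t(vapply(cons, function(b) {
      p <- rep((1 - prob) / 3, 4)
      p[match(b, bases)] <- prob
      p
    }, numeric(4)))
  }
  pwm <- unname(as.matrix(pwm))
  if (ncol(pwm) != 4 || any(pwm < 0) || any(abs(rowSums(pwm) - 1) > 1e-9)) {
    abort("motif_model: each PWM row must be a probability vector over A,C,G,T")
  }
  colnames(pwm) <- bases
  ic <- apply(pwm, 1, function(p) {
    2 + sum(ifelse(p > 0, p * log2(p), 0))
  })
  cons <- paste(bases[max.col(pwm)], collapse = "")
  structure(list(pwm = pwm, consensus = cons, ic = ic, name = name),
            class = "motif_model")
}

#' The default planted motif
#'
#' An 8-bp point-mass consensus (`TGACTCAG`, an AP-1-like core extended to
#' 8 bp), 2 bits per column: strong enough that a sequence classifier can
#' recover it from a few hundred training examples.
#'
#' @return A `motif_model`.
#' @export
default_motif <- function() motif_model("TGACTCAG", name = "consensus8")

#' @export
print.motif_model <- function(x, ...) {
  cat("<motif_model>", x$name, " W =", nrow(x$pwm),
      " consensus =", x$consensus,
      sprintf(" IC = %.1f bits\n", sum(x$ic)))
  invisible(x)
}

#' Specify a synthetic binding-site dataset
#'
#' Emulates a ChIP-seq-style labelled set: fixed-length positives carrying
#' one planted motif instance at a uniformly random offset over an i.i.d.
#' background, and negatives matched to the positives in length and
#' composition — either i.i.d. draws from the positives' empirical
#' mononucleotide frequencies (`composition_matched`) or
#' dinucleotide-preserving shuffles of sampled positives
#' (`dinucleotide_shuffle`, which also preserves local repeat structure).
#' Negatives containing a near-complete motif consensus match are rejected
#' and redrawn.
#'
#' @param n_pos,n_neg Numbers of positive and negative sequences
#'   (defaults 1000 each).
#' @param seq_length Sequence length in bp (default 101).
#' @param motif A [motif_model()], or `NULL` to disable planting (positives
#'   become pure background; a null/no-signal dataset).
#' @param background Base-composition probabilities for A, C, G, T
#'   (default uniform).
#' @param negative_mode `"composition_matched"` (default) or
#'   `"dinucleotide_shuffle"`.
#' @param seed Integer seed; the generated dataset is a pure function of
#'   the spec.
#' @return A `synthetic_spec` object.
#' @export
synthetic_spec <- function(n_pos = 1000L, n_neg = 1000L, seq_length = 101L,
                           motif = default_motif(),
                           background = c(0.25, 0.25, 0.25, 0.25),
                           negative_mode = c("composition_matched",
                                             "dinucleotide_shuffle"),
                           seed = 1L) {
  negative_mode <- match.arg(negative_mode)
  if (n_pos < 1 || n_neg < 1) abort("n_pos and n_neg must be >= 1")
  if (abs(sum(background) - 1) > 1e-9 || any(background < 0)) {
    abort("background must be a probability vector over A,C,G,T")
  }
  if (!is.null(motif)) {
    stopifnot(inherits(motif, "motif_model"))
    if (nrow(motif$pwm) > seq_length) {
      abort("motif is longer than seq_length")
    }
  }
  structure(
    list(n_pos = as.integer(n_pos), n_neg = as.integer(n_neg),
         seq_length = as.integer(seq_length), motif = motif,
         background = background, negative_mode = negative_mode,
         seed = as.integer(seed)),
    class = "synthetic_spec"
  )
}

BASES <- c("A", "C", "G", "T")

draw_background <- function(n, L, background) {
  m <- matrix(sample(BASES, n * L, replace = TRUE, prob = background),
              nrow = n, ncol = L)
  m
}

#' Sample motif-bearing positive sequences
#'
#' Draws background bases i.i.d. from the spec's base composition, then
#' plants one motif instance (drawn column-wise from the PWM) at a
#' uniformly random offset. Uses the current RNG state; seed control
#' belongs to the caller (see [generate_dataset()]).
#'
#' @param spec A [synthetic_spec()].
#' @param n Number of sequences.
#' @return A tibble with `sequence` and `motif_offset` (0-based start of
#'   the planted instance; `NA` when the spec has no motif).
#' @export
sample_positive <- function(spec, n = 1L) {
  stopifnot(inherits(spec, "synthetic_spec"))
  L <- spec$seq_length
  m <- draw_background(n, L, spec$background)
  offsets <- rep(NA_integer_, n)
  if (!is.null(spec$motif)) {
    W <- nrow(spec$motif$pwm)
    offsets <- sample.int(L - W + 1L, n, replace = TRUE) - 1L
    inst <- apply(spec$motif$pwm, 1, function(p) {
      sample(BASES, n, replace = TRUE, prob = p)
    })
    inst <- matrix(inst, nrow = n)  # n x W
    for (i in seq_len(n)) {
      m[i, (offsets[i] + 1):(offsets[i] + W)] <- inst[i, ]
    }
  }
  tibble::tibble(
    sequence = apply(m, 1, paste, collapse = ""),
    motif_offset = offsets
  )
}

# Consensus rejection: TRUE if the sequence contains the full consensus or
# either of its two (W-1)-length sub-windows.
contains_near_consensus <- function(sequence, motif) {
  if (is.null(motif)) return(rep(FALSE, length(sequence)))
  cons <- motif$consensus
  W <- nchar(cons)
  pats <- cons
  if (W >= 2) {
    pats <- unique(c(cons, substr(cons, 1, W - 1), substr(cons, 2, W)))
  }
  Reduce(`|`, lapply(pats, function(p) grepl(p, sequence, fixed = TRUE)))
}

#' Dinucleotide-preserving shuffle of one DNA sequence
#'
#' Altschul-Erickson Euler-path shuffle: the output is a random sequence
#' with exactly the same dinucleotide counts (and hence mononucleotide
#' counts up to end effects) as the input.
#'
#' @param sequence A DNA string.
#' @return A shuffled string of the same length.
#' @export
dinucleotide_shuffle <- function(sequence) {
  s <- strsplit(sequence, "")[[1]]
  n <- length(s)
  if (n <= 3) return(sequence)
  verts <- unique(s)
  if (length(verts) == 1) return(sequence)
  last <- s[n]
  # outgoing edge lists per vertex
  edges <- split(s[-1], factor(s[-n], levels = verts))
  for (attempt in 1:100) {
    # choose a random "last edge" for every vertex except the end vertex
    last_edge <- vapply(verts, function(v) {
      if (v == last || length(edges[[v]]) == 0) NA_character_
      else sample(edges[[v]], 1)
    }, character(1))
    # the chosen edges must connect every such vertex to the end vertex
    reach <- function(v) {
      seen <- character(0)
      while (!is.na(v) && !(v %in% seen)) {
        if (v == last) return(TRUE)
        seen <- c(seen, v)
        v <- if (v %in% verts) last_edge[[v]] else NA_character_
      }
      FALSE
    }
    ok <- all(vapply(verts[verts != last & lengths(edges)[verts] > 0],
                     reach, logical(1)))
    if (ok) break
  }
  if (!ok) return(paste(sample(s), collapse = ""))  # degenerate fallback
  shuffled <- lapply(verts, function(v) {
    e <- edges[[v]]
    if (length(e) == 0) return(e)
    if (v == last) return(sample(e, length(e)))
    le <- last_edge[[v]]
    pos <- match(le, e)
    rest <- e[-pos]
    c(if (length(rest) > 1) sample(rest, length(rest)) else rest, le)
  })
  names(shuffled) <- verts
  ptr <- setNames(rep(1L, length(verts)), verts)
  out <- character(n)
  out[1] <- s[1]
  v <- s[1]
  for (i in 2:n) {
    nx <- shuffled[[v]][ptr[[v]]]
    ptr[[v]] <- ptr[[v]] + 1L
    out[i] <- nx
    v <- nx
  }
  paste(out, collapse = "")
}

#' Sample composition-matched negative sequences
#'
#' `composition_matched`: i.i.d. draws from the empirical mononucleotide
#' frequencies of the positives; `dinucleotide_shuffle`: a
#' dinucleotide-preserving shuffle of a randomly sampled positive. Either
#' way the length equals the positives' length, and any candidate
#' containing a `>= (W - 1)`-length match to the motif consensus is
#' rejected and redrawn (at most 1000 attempts per sequence).
#'
#' @param spec A [synthetic_spec()].
#' @param positives Character vector of positive sequences (or the tibble
#'   from [sample_positive()]).
#' @param n Number of negatives.
#' @return A tibble with a `sequence` column.
#' @export
sample_negative <- function(spec, positives, n = 1L) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (is.data.frame(positives)) positives <- positives$sequence
  if (length(positives) == 0) abort("sample_negative: no positives supplied")
  L <- spec$seq_length
  if (spec$negative_mode == "composition_matched") {
    counts <- table(factor(strsplit(paste(positives, collapse = ""), "")[[1]],
                           levels = BASES))
    freq <- as.numeric(counts) / sum(counts)
    draw <- function(m) {
      mat <- draw_background(m, L, freq)
      apply(mat, 1, paste, collapse = "")
    }
  } else {
    draw <- function(m) {
      src <- positives[sample.int(length(positives), m, replace = TRUE)]
      vapply(src, dinucleotide_shuffle, character(1), USE.NAMES = FALSE)
    }
  }
  out <- character(0)
  attempts <- 0L
  while (length(out) < n) {
    need <- n - length(out)
    cand <- draw(need)
    keep <- !contains_near_consensus(cand, spec$motif)
    out <- c(out, cand[keep])
    attempts <- attempts + 1L
    if (attempts > 1000L) {
      abort(paste0(
        "sample_negative: rejection sampling exceeded 1000 rounds; ",
        "use a weaker/shorter motif or longer sequences"
      ))
    }
  }
  tibble::tibble(sequence = out[seq_len(n)])
}

#' Generate a complete synthetic labelled dataset
#'
#' `n_pos` motif-bearing positives (label 1) and `n_neg` matched negatives
#' (label 0), shuffled deterministically under the spec's seed. The planted
#' motif offset of each positive is kept as truth metadata.
#'
#' @param spec A [synthetic_spec()].
#' @return A labelled dataset tibble (`id`, `sequence`, `label`,
#'   `motif_offset`) with the spec attached as attribute `spec`.
#' @examples
#' d <- generate_dataset(synthetic_spec(n_pos = 5, n_neg = 5, seed = 42))
#' table(d$label)
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_seed(spec$seed, {
    pos <- sample_positive(spec, spec$n_pos)
    neg <- sample_negative(spec, pos$sequence, spec$n_neg)
    data <- tibble::tibble(
      id = c(sprintf("pos_%04d", seq_len(spec$n_pos)),
             sprintf("neg_%04d", seq_len(spec$n_neg))),
      sequence = c(pos$sequence, neg$sequence),
      label = c(rep(1L, spec$n_pos), rep(0L, spec$n_neg)),
      motif_offset = c(pos$motif_offset, rep(NA_integer_, spec$n_neg))
    )
    data <- data[sample.int(nrow(data)), ]
  })
  attr(data, "spec") <- spec
  validate_dataset(data)
  data
}
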