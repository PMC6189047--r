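test_that("motif_model builds a valid PWM with information content", {
  m <- motif_model("ACGTACGT")
  expect_equal(dim(m$pwm), c(8, 4))
  expect_equal(rowSums(m$pwm), rep(1, 8), ignore_attr = TRUE)
  expect_equal(m$ic, rep(2, 8), ignore_attr = TRUE)  # point mass: 2 bits
  soft <- motif_model("ACGT", prob = 0.7)
  expect_equal(unname(soft$pwm[1, "A"]), 0.7)
  expect_true(all(soft$ic < 2))
  expect_error(motif_model("ACGX"), "ACGT")
  expect_error(motif_model(pwm = matrix(0.3, 2, 4)), "probability")
})

test_that("positives have the right length and contain the planted consensus", {
  spec <- synthetic_spec(n_pos = 50, n_neg = 50,
                         motif = motif_model("ACGTACGT"), seed = 1)
  pos <- withr::with_seed(1, sample_positive(spec, 50))
  expect_true(all(nchar(pos$sequence) == 101))
  expect_true(all(grepl("ACGTACGT", pos$sequence, fixed = TRUE)))
  # recorded offsets point at the instance
  expect_true(all(substr(pos$sequence, pos$motif_offset + 1,
                         pos$motif_offset + 8) == "ACGTACGT"))
})

test_that("composition-matched negatives exclude the consensus and match GC", {
  spec <- synthetic_spec(n_pos = 500, n_neg = 500, seed = 3,
                         background = c(0.2, 0.3, 0.3, 0.2))
  d <- generate_dataset(spec)
  pos <- d$sequence[d$label == 1]
  neg <- d$sequence[d$label == 0]
  expect_false(any(grepl(spec$motif$consensus, neg, fixed = TRUE)))
  gc <- function(x) {
    mean(vapply(strsplit(x, ""), function(s) mean(s %in% c("G", "C")),
                numeric(1)))
  }
  expect_lt(abs(gc(neg) - gc(pos)), 0.02)
  expect_true(all(nchar(neg) == 101))
})

test_that("dinucleotide shuffle preserves dinucleotide counts exactly", {
  withr::with_seed(9, {
    for (i in 1:20) {
      x <- paste(sample(c("A", "C", "G", "T"), 80, replace = TRUE),
                 collapse = "")
      y <- dinucleotide_shuffle(x)
      expect_equal(nchar(y), nchar(x))
      expect_equal(dinuc_counts(y), dinuc_counts(x))
    }
    # shuffle-mode negatives inherit the guarantee
    spec <- synthetic_spec(n_pos = 20, n_neg = 20,
                           negative_mode = "dinucleotide_shuffle", seed = 4)
    d <- generate_dataset(spec)
    expect_true(all(nchar(d$sequence) == 101))
    expect_false(any(grepl(spec$motif$consensus, d$sequence[d$label == 0],
                           fixed = TRUE)))
  })
})

test_that("generate_dataset is deterministic and correctly labelled", {
  spec <- synthetic_spec(n_pos = 40, n_neg = 60, seed = 11)
  a <- generate_dataset(spec)
  b <- generate_dataset(spec)
  expect_identical(a$sequence, b$sequence)
  expect_identical(a$id, b$id)
  expect_equal(sum(a$label == 1), 40)
  expect_equal(sum(a$label == 0), 60)
  expect_false(identical(a$sequence,
                         generate_dataset(synthetic_spec(40, 60, seed = 12))$sequence))
  # byte-identical FASTA output
  p1 <- file.path(withr::local_tempdir(), "a")
  p2 <- file.path(withr::local_tempdir(), "b")
  write_dataset(a, p1)
  write_dataset(b, p2)
  expect_identical(readLines(paste0(p1, ".fa")), readLines(paste0(p2, ".fa")))
})

test_that("generated records tokenize to 49 five-mers at stride 2", {
  d <- generate_dataset(synthetic_spec(n_pos = 5, n_neg = 5, seed = 2))
  expect_true(all(lengths(tokenize(d, 5, 2)$tokens) == 49))
})

test_that("an over-strong motif in short sequences trips the rejection guard", {
  # a 1-bp 'motif' matches everywhere: every negative candidate is rejected
  spec <- synthetic_spec(n_pos = 2, n_neg = 2, seq_length = 5,
                         motif = motif_model("A"), seed = 1)
  pos <- withr::with_seed(1, sample_positive(spec, 5))
  expect_error(withr::with_seed(1, sample_negative(spec, rep("AAAAA", 5), 2)),
               "1000")
  expect_error(synthetic_spec(seq_length = 4, motif = motif_model("ACGTACGT")),
               "longer")
})
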