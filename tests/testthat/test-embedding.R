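test_that("build_corpus yields one sentence per record, order preserved", {
  d1 <- toy_dataset(n = 3, L = 21, seed = 1)
  d2 <- toy_dataset(n = 4, L = 21, seed = 2)
  corpus <- build_corpus(list(d1, d2), k = 3, s = 2)
  expect_length(corpus, 7)
  expect_true(all(lengths(corpus) == n_kmers(21, 3, 2)))
  expect_identical(corpus[[1]], split_kmers(d1$sequence[1], 3, 2))
  expect_identical(corpus, build_corpus(list(d1, d2), k = 3, s = 2))
  expect_error(build_corpus(list(), 3, 2), "empty")
})

test_that("embedding matrix has padding row zero and the contract shape", {
  d <- toy_dataset(n = 10, L = 101, seed = 3)
  emb <- train_kmer_embedding(build_corpus(d, 5, 2), d = 50, seed = 1)
  expect_equal(dim(emb$matrix), c(1025, 50))
  expect_equal(emb$matrix[1, ], rep(0, 50), ignore_attr = TRUE)
  expect_true(all(is.finite(emb$matrix)))
  expect_equal(emb$provenance$source, "pretrained")
})

test_that("embedding training is reproducible under a fixed seed", {
  d <- toy_dataset(n = 8, L = 60, seed = 4)
  corpus <- build_corpus(d, 3, 2)
  a <- train_kmer_embedding(corpus, d = 16, seed = 42)
  b <- train_kmer_embedding(corpus, d = 16, seed = 42)
  expect_identical(a$matrix, b$matrix)
  c2 <- train_kmer_embedding(corpus, d = 16, seed = 43)
  expect_false(identical(a$matrix, c2$matrix))
})

test_that("co-occurring token groups end up closer than non-co-occurring ones", {
  # two-block corpus: sentences use {A,C} only or {G,T} only, so A-C
  # co-occur within every window but never with G or T
  cos <- function(a, b) sum(a * b) / sqrt(sum(a * a) * sum(b * b))
  for (seed in 1:5) {
    sentences <- withr::with_seed(seed, {
      lapply(1:200, function(i) {
        if (i %% 2 == 0) sample(c("A", "C"), 20, replace = TRUE)
        else sample(c("G", "T"), 20, replace = TRUE)
      })
    })
    emb <- train_kmer_embedding(sentences, vocab = kmer_vocab(1), d = 16,
                                epochs = 5, seed = seed)
    vec <- function(tok) emb$matrix[encode_kmers(tok, emb$vocab) + 1, ]
    within <- mean(c(cos(vec("A"), vec("C")), cos(vec("G"), vec("T"))))
    between <- mean(c(cos(vec("A"), vec("G")), cos(vec("A"), vec("T")),
                      cos(vec("C"), vec("G")), cos(vec("C"), vec("T"))))
    expect_gt(within, between)
  }
})

test_that("embedding_lookup returns rows, zeros for padding, linear in one-hots", {
  d <- toy_dataset(n = 5, L = 101, seed = 6)
  emb <- train_kmer_embedding(build_corpus(d, 5, 2), d = 50, seed = 2)
  idx <- encode_kmers(split_kmers(d$sequence[1], 5, 2), emb$vocab)
  out <- embedding_lookup(idx, emb)
  expect_equal(dim(out), c(49, 50))
  expect_equal(embedding_lookup(c(0L, 0L, 0L), emb),
               matrix(0, 3, 50), ignore_attr = TRUE)
  i <- 17L
  onehot <- replace(numeric(nrow(emb$matrix)), i + 1, 1)
  expect_equal(embedding_lookup(i, emb)[1, ], drop(onehot %*% emb$matrix))
  expect_error(embedding_lookup(9999L, emb), "out of range")
})

test_that("embedding strategies satisfy their init/trainable contracts", {
  d <- toy_dataset(n = 6, L = 41, seed = 7)
  pre <- train_kmer_embedding(build_corpus(d, 2, 2), d = 8, seed = 3)
  frozen <- embedding_layer("init_no_train", pretrained = pre)
  expect_identical(frozen$weights, unname(pre$matrix))
  expect_false(frozen$trainable)
  tuned <- embedding_layer("init_train", pretrained = pre)
  expect_identical(tuned$weights, unname(pre$matrix))
  expect_true(tuned$trainable)
  r1 <- embedding_layer("no_init", V = 16, d = 8, seed = 7)
  r2 <- embedding_layer("no_init", V = 16, d = 8, seed = 7)
  expect_identical(r1$weights, r2$weights)
  expect_true(r1$trainable)
  expect_equal(r1$weights[1, ], rep(0, 8))
  expect_true(all(abs(r1$weights) <= 0.05))
  expect_error(embedding_layer("init_train"), "pretrained")
  expect_error(embedding_layer("init_train", pretrained = pre, d = 16),
               "dimension")
})

test_that("embedding serialization round-trips matrix and provenance", {
  d <- toy_dataset(n = 5, L = 31, seed = 8)
  emb <- train_kmer_embedding(build_corpus(d, 2, 2), d = 6, seed = 9)
  prefix <- file.path(withr::local_tempdir(), "emb")
  write_embedding(emb, prefix)
  back <- read_embedding(prefix)
  expect_equal(back$matrix, emb$matrix)
  expect_equal(back$vocab$tokens, emb$vocab$tokens)
  expect_equal(back$provenance$seed, emb$provenance$seed)
})
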