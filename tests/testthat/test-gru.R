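test_that("gru_step with all-zero parameters halves the previous state", {
  p <- gru_params(units = 4, input_dim = 3, seed = 1)
  for (nm in names(p)) p[[nm]][] <- 0
  h_prev <- c(0.3, -0.8, 0, 1)
  expect_equal(gru_step(rnorm(3), h_prev, p), 0.5 * h_prev)
  expect_equal(gru_step(numeric(3), numeric(4), p), numeric(4))
})

test_that("gru_step matches the scalar hand evaluation at units=d=1", {
  p <- gru_params(1, 1, seed = 1)
  for (nm in c("W_z", "U_z", "W_r", "U_r", "W_h", "U_h")) p[[nm]][] <- 1
  for (nm in c("b_z", "b_r", "b_h")) p[[nm]][] <- 0
  # independent scalar calculation
  z <- 1 / (1 + exp(-2))
  r <- 1 / (1 + exp(-2))
  m <- tanh(1 + r * 1)
  h_expect <- (1 - z) * 1 + z * m
  expect_equal(gru_step(1, 1, p), h_expect, tolerance = 1e-12)
  expect_equal(z, 0.880797, tolerance = 1e-6)
})

test_that("vectorized gru_step equals the scalar loop oracle", {
  withr::with_seed(11, {
    for (i in 1:200) {
      units <- sample(1:8, 1)
      d <- sample(1:8, 1)
      p <- random_gru_params(units, d)
      x <- rnorm(d)
      h <- runif(units, -1, 1)
      expect_equal(gru_step(x, h, p), gru_step_oracle(x, h, p),
                   tolerance = 1e-6)
    }
  })
})

test_that("update-gate degeneracies pin h_t to h_prev or m_t", {
  withr::with_seed(12, {
    for (i in 1:25) {
      units <- sample(1:6, 1); d <- sample(1:6, 1)
      p <- random_gru_params(units, d)
      x <- rnorm(d); h <- runif(units, -1, 1)
      pz0 <- p; pz0$b_z[] <- -1e9       # z -> 0: state carried through
      expect_equal(gru_step(x, h, pz0), h)
      pz1 <- p; pz1$b_z[] <- 1e9        # z -> 1: state replaced by candidate
      m <- tanh(drop(p$W_h %*% x + p$U_h %*%
                       (sigmoid_ref(drop(p$W_r %*% x + p$U_r %*% h) + p$b_r) * h)) +
                  p$b_h)
      expect_equal(gru_step(x, h, pz1), m)
    }
  })
})

test_that("hidden states stay in [-1, 1] when started there", {
  withr::with_seed(13, {
    for (i in 1:100) {
      units <- sample(1:6, 1); d <- sample(1:6, 1)
      p <- random_gru_params(units, d)
      h <- runif(units, -1, 1)
      for (t in 1:10) {
        h <- gru_step(rnorm(d, sd = 3), h, p)
        expect_true(all(abs(h) <= 1))
      }
    }
  })
})

test_that("gru_step rejects shape mismatch and non-finite input", {
  p <- gru_params(3, 2)
  expect_error(gru_step(c(1, 2, 3), numeric(3), p), "shape")
  expect_error(gru_step(c(1, NA), numeric(3), p), "finite")
})

test_that("run_bigru at length 1 gives equal direction states", {
  vocab <- kmer_vocab(1)
  m <- bigru_model(vocab, embedding_layer("no_init", V = 4, d = 3, seed = 2),
                   units = 5, merge_mode = "sum", seed = 3)
  # force both directions to share parameters so fout == bout exactly
  m$layers[[1]]$bwd <- m$layers[[1]]$fwd
  x <- matrix(rnorm(3), 1, 3)
  out <- run_bigru(x, model = m)
  fwd_only <- gru_step(drop(x), numeric(5), m$layers[[1]]$fwd)
  expect_equal(out, 2 * fwd_only)
})

test_that("merge modes obey their dimension and algebra contracts", {
  vocab <- kmer_vocab(1)
  emb <- embedding_layer("no_init", V = 4, d = 4, seed = 5)
  x <- matrix(rnorm(12), 3, 4)
  outs <- lapply(c("concatenate", "sum", "average", "multiplication"),
                 function(mm) {
    m <- bigru_model(vocab, emb, units = 6, merge_mode = mm, seed = 9)
    run_bigru(x, model = m)
  })
  names(outs) <- c("concatenate", "sum", "average", "multiplication")
  expect_length(outs$concatenate, 12)
  expect_length(outs$sum, 6)
  expect_equal(outs$average, outs$sum / 2)
  expect_equal(outs$sum, outs$concatenate[1:6] + outs$concatenate[7:12])
  expect_equal(outs$multiplication,
               outs$concatenate[1:6] * outs$concatenate[7:12])
})

test_that("padding steps never change the merged output", {
  vocab <- kmer_vocab(1)
  m <- bigru_model(vocab, embedding_layer("no_init", V = 4, d = 3, seed = 6),
                   units = 4, seed = 7)
  withr::with_seed(14, {
    for (i in 1:50) {
      N <- sample(2:12, 1)
      pad <- sample(1:10, 1)
      x <- matrix(rnorm(N * 3), N, 3)
      xp <- rbind(x, matrix(rnorm(pad * 3), pad, 3))
      base <- run_bigru(x, model = m)
      padded <- run_bigru(xp, mask = c(rep(TRUE, N), rep(FALSE, pad)),
                          model = m)
      expect_identical(padded, base)
    }
  })
  expect_error(run_bigru(matrix(0, 2, 3), mask = c(FALSE, FALSE), model = m),
               "masked")
})

test_that("predict_proba composes embed -> BiGRU -> dense -> sigmoid", {
  vocab <- kmer_vocab(2)
  m <- bigru_model(vocab, embedding_layer("no_init", V = 16, d = 5, seed = 8),
                   units = 4, seed = 10)
  idx <- encode_kmers(split_kmers("ACGTACGTAC", 2, 1), vocab)
  p <- predict_proba(as.integer(idx), m)
  # manual composition
  merged <- run_bigru(embedding_lookup(idx, m$embedding$weights), model = m)
  expect_equal(p, sigmoid_ref(sum(merged * m$head$beta) + m$head$bias))
  # beta = 0, bias = 0 -> 0.5 everywhere
  m0 <- m; m0$head$beta[] <- 0; m0$head$bias <- 0
  expect_equal(predict_proba(as.integer(idx), m0), 0.5)
  # monotone in bias
  m1 <- m; m1$head$bias <- m$head$bias + 1
  expect_gt(predict_proba(as.integer(idx), m1), p)
})

test_that("batch prediction equals per-sequence prediction", {
  vocab <- kmer_vocab(2)
  m <- bigru_model(vocab, embedding_layer("no_init", V = 16, d = 5, seed = 1),
                   units = 6, seed = 2)
  withr::with_seed(15, {
    seqs <- lapply(1:8, function(i) sample.int(16, sample(4:10, 1), replace = TRUE))
  })
  batch <- predict_proba(seqs, m)
  single <- vapply(seqs, predict_proba, numeric(1), model = m)
  expect_equal(batch, single, tolerance = 1e-5)
})

test_that("loss evaluates the clipped Bernoulli negative log-likelihood", {
  expect_equal(bce_loss(0.5, 1), -log(0.5))
  expect_equal(bce_loss(1 - 1e-7, 1), 1e-7, tolerance = 1e-6)
  expect_equal(bce_loss(c(0.9, 0.1), c(1, 0)), -2 * log(0.9))
  expect_equal(bce_loss(c(0.9, 0.1), c(1, 0)), 0.210721, tolerance = 1e-6)
  expect_gte(bce_loss(1, 1), 0)  # clipping keeps the loss finite
  expect_true(is.finite(bce_loss(c(0, 1), c(1, 0))))
  expect_error(bce_loss(0.5, c(1, 0)), "length")
})

test_that("analytic gradients match finite differences", {
  vocab <- kmer_vocab(1)
  emb <- embedding_layer("no_init", V = 4, d = 3, seed = 11)
  m <- bigru_model(vocab, emb, units = 3, merge_mode = "concatenate",
                   seed = 5)
  withr::with_seed(16, {
    idx <- matrix(sample(1:4, 8, replace = TRUE), 2, 4)
  })
  mask <- matrix(c(1, 1, 1, 0, 1, 1, 1, 1), 2, 4, byrow = TRUE)
  y <- c(1, 0)
  lossfn <- function(mod) {
    fw <- kmergru:::forward_model(mod, idx, mask)
    bce_loss(fw$p, y) / 2
  }
  fw <- kmergru:::forward_model(m, idx, mask, keep_cache = TRUE)
  gr <- kmergru:::backward_model(m, fw, (fw$p - y) / 2)
  flat <- kmergru:::model_flat_params(m)
  for (nm in names(flat)) {
    n_check <- min(length(flat[[nm]]), 6)
    for (i in seq_len(n_check)) {
      if (nm == "emb" && (i - 1) %% nrow(flat$emb) == 0) next  # frozen pad row
      eps <- 1e-6
      f2 <- flat
      f2[[nm]][i] <- f2[[nm]][i] + eps
      up <- lossfn(kmergru:::model_set_flat(m, f2))
      f2[[nm]][i] <- f2[[nm]][i] - 2 * eps
      dn <- lossfn(kmergru:::model_set_flat(m, f2))
      expect_lt(abs(gr[[nm]][i] - (up - dn) / (2 * eps)), 1e-6)
    }
  }
})
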