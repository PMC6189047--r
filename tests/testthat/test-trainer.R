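make_motif_data <- function(n_pos = 150, n_neg = 150, seed = 21) {
  d <- generate_dataset(synthetic_spec(n_pos = n_pos, n_neg = n_neg,
                                       seed = seed))
  split_dataset(d, seed = seed)
}

test_that("training reduces the loss on a learnable task", {
  d <- make_motif_data(100, 100, seed = 31)
  cfg <- train_config(units = 16, optimizer = "Adam", epochs = 4,
                      batch_size = 40, d = 16, patience = Inf, seed = 5)
  fit <- fit_bigru(d, cfg)
  expect_lt(tail(fit$history$loss, 1), fit$history$loss[1])
  expect_equal(nrow(fit$history), 4)
  expect_true(all(c("epoch", "loss", "val_auc") %in% names(fit$history)))
})

test_that("config validation rejects degenerate settings", {
  expect_error(train_config(epochs = 0), "epochs")
  expect_error(train_config(batch_size = 0), "batch_size")
  expect_error(train_config(optimizer = "adamw"), "optimizer")
  expect_error(train_config(merge_mode = "max"), "merge")
  expect_error(train_config(embedding_strategy = "frozen"), "strategy")
})

test_that("fixed seed reproduces the loss trajectory exactly", {
  d <- make_motif_data(60, 60, seed = 32)
  cfg <- train_config(units = 8, epochs = 2, batch_size = 30, d = 8,
                      patience = Inf, seed = 9)
  f1 <- fit_bigru(d, cfg)
  f2 <- fit_bigru(d, cfg)
  expect_identical(f1$history$loss, f2$history$loss)
  expect_identical(f1$model$head$beta, f2$model$head$beta)
  cfg2 <- cfg; cfg2$seed <- 10L
  expect_false(identical(f1$history$loss[1], fit_bigru(d, cfg2)$history$loss[1]))
})

test_that("each optimizer takes a descent step on a linear toy problem", {
  withr::with_seed(33, {
    X <- rbind(matrix(rnorm(40, mean = 2), 20, 2),
               matrix(rnorm(40, mean = -2), 20, 2))
    y <- rep(c(1, 0), each = 20)
    for (opt_name in c("SGD", "Adam", "Adagrad", "RMSprop")) {
      params <- list(w = c(0, 0), b = 0)
      opt <- kmergru:::make_optimizer(opt_name)
      loss_at <- function(p) bce_loss(sigmoid_ref(X %*% p$w + p$b), y)
      l0 <- loss_at(params)
      for (it in 1:50) {
        p <- sigmoid_ref(X %*% params$w + params$b)
        g <- drop(p - y) / length(y)
        params <- opt$step(params, list(w = drop(crossprod(X, g)), b = sum(g)))
      }
      expect_lt(loss_at(params), l0)
    }
  })
})

test_that("early stopping restores the best-validation-AUC weights", {
  d <- make_motif_data(80, 80, seed = 34)
  cfg <- train_config(units = 8, epochs = 6, batch_size = 40, d = 8,
                      patience = 2, seed = 4)
  fit <- fit_bigru(d, cfg)
  expect_equal(fit$val_auc, max(fit$history$val_auc))
  expect_equal(fit$best_epoch, which.max(fit$history$val_auc))
  # restored weights reproduce the best epoch's validation AUC
  ev <- evaluate_model(fit, d, "validation")
  expect_equal(ev$auc, fit$val_auc)
})

test_that("a frozen embedding stays bit-identical through training", {
  d <- make_motif_data(60, 60, seed = 35)
  corpus <- build_corpus(d[d$split == "train", ], 5, 2)
  pre <- train_kmer_embedding(corpus, d = 8, seed = 2)
  cfg <- train_config(units = 8, epochs = 2, batch_size = 30, d = 8,
                      embedding_strategy = "init_no_train", patience = Inf,
                      seed = 3)
  fit <- fit_bigru(d, cfg, pretrained = pre)
  expect_identical(fit$model$embedding$weights, unname(pre$matrix))
})

test_that("a fine-tuned embedding starts at the pretrained matrix and moves", {
  d <- make_motif_data(60, 60, seed = 36)
  corpus <- build_corpus(d[d$split == "train", ], 5, 2)
  pre <- train_kmer_embedding(corpus, d = 8, seed = 2)
  cfg <- train_config(units = 8, epochs = 1, batch_size = 120, d = 8,
                      embedding_strategy = "init_train", patience = Inf,
                      seed = 3)
  fit <- fit_bigru(d, cfg, pretrained = pre)
  expect_false(identical(fit$model$embedding$weights, unname(pre$matrix)))
  # step 0 fidelity
  layer <- embedding_layer("init_train", pretrained = pre)
  expect_identical(layer$weights, unname(pre$matrix))
})

test_that("the default grid has exactly the 12 units-optimizer combinations", {
  grid <- default_grid(train_config(epochs = 1))
  expect_length(grid, 12)
  combos <- unique(t(vapply(grid, function(g) c(g$units, g$optimizer),
                            character(2))))
  expect_equal(nrow(combos), 12)
  expect_setequal(unique(combos[, 1]), c("50", "80", "100"))
  expect_setequal(unique(combos[, 2]), c("SGD", "Adam", "Adagrad", "RMSprop"))
})

test_that("grid_search evaluates every cell once and breaks ties as stated", {
  d <- make_motif_data(60, 60, seed = 37)
  grid <- default_grid(train_config(units = 4, epochs = 1, batch_size = 30,
                                    d = 8, seed = 6), units = c(4L, 6L),
                       optimizers = c("Adam", "SGD"))
  res <- grid_search(d, grid)
  expect_equal(nrow(res$report), 4)
  expect_equal(sum(res$report$status == "ok"), 4)
  # tie-break rule: equal AUC -> higher APS -> smaller units
  rep <- res$report
  rep$auc <- c(0.9, 0.9, 0.9, 0.8)
  rep$aps <- c(0.7, 0.8, 0.8, 0.9)
  rep$units <- c(4L, 6L, 4L, 6L)
  ok <- seq_len(4)
  sel <- ok[order(-rep$auc[ok], -rep$aps[ok], rep$units[ok])][1]
  expect_equal(sel, 3)
  # serialization round-trip of the report
  f <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(res$report, f)
  back <- readr::read_tsv(f, show_col_types = FALSE)
  expect_equal(as.data.frame(back), as.data.frame(res$report))
})

test_that("a failing grid cell is flagged without aborting the others", {
  d <- make_motif_data(40, 40, seed = 38)
  bad <- train_config(units = 4, epochs = 1, batch_size = 30, d = 8, seed = 6)
  bad$d <- -5L  # corrupt one cell after validation
  grid <- list(bad, train_config(units = 4, epochs = 1, batch_size = 30,
                                 d = 8, seed = 6))
  res <- grid_search(d, grid)
  expect_match(res$report$status[1], "failed")
  expect_equal(res$report$status[2], "ok")
  expect_equal(res$best_index, 2)
})

test_that("embedding-strategy comparison reports three strategies twice", {
  d <- make_motif_data(60, 60, seed = 39)
  rep <- compare_embedding_strategies(
    d, train_config(units = 6, epochs = 1, batch_size = 30, d = 8, seed = 2))
  expect_equal(nrow(rep), 6)  # 3 strategies x validation/test
  expect_setequal(unique(rep$strategy),
                  c("no_init", "init_no_train", "init_train"))
  expect_true(all(is.finite(rep$auc)) && all(rep$auc >= 0 & rep$auc <= 1))
})

test_that("sensitivity sweeps retokenize per value and report summaries", {
  d <- make_motif_data(40, 40, seed = 40)
  cfg <- train_config(units = 4, epochs = 1, batch_size = 40, d = 8, seed = 3)
  sk <- sensitivity_sweep(d, "k", c(4, 5), cfg)
  expect_equal(sk$vocab_size, c(256, 1024))
  expect_equal(nrow(sk), 2)
  sd_ <- sensitivity_sweep(d, "d", c(8, 12), cfg)
  expect_equal(nrow(sd_), 2)
  expect_true(all(c("mean_auc", "median_auc") %in% names(sd_)))
})

test_that("tidy and glance expose history and model-level summaries", {
  d <- make_motif_data(40, 40, seed = 41)
  fit <- fit_bigru(d, train_config(units = 4, epochs = 2, batch_size = 40,
                                   d = 8, patience = Inf, seed = 1))
  td <- tidy(fit)
  expect_equal(nrow(td), 2)
  gl <- glance(fit)
  expect_equal(gl$epochs_run, 2L)
  expect_gt(gl$n_parameters, 0)
})
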