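# Independent oracles used across tests. These deliberately re-derive the
# quantities with straight-line / brute-force code and must stay free of
# the package's own implementation paths.

sigmoid_ref <- function(x) 1 / (1 + exp(-x))

# Eq-style window count by explicit enumeration.
count_windows_brute <- function(L, k, s) {
  n <- 0L
  t <- 0L
  while (t * s + k <= L) {
    n <- n + 1L
    t <- t + 1L
  }
  n
}

# Scalar, loop-based GRU step: update gate, reset gate, candidate state,
# convex combination — one component at a time.
gru_step_oracle <- function(x_t, h_prev, params) {
  units <- length(h_prev)
  d <- length(x_t)
  sig <- function(v) 1 / (1 + exp(-v))
  h_t <- numeric(units)
  z <- numeric(units); r <- numeric(units)
  for (i in seq_len(units)) {
    az <- params$b_z[i]; ar <- params$b_r[i]
    for (j in seq_len(d)) {
      az <- az + params$W_z[i, j] * x_t[j]
      ar <- ar + params$W_r[i, j] * x_t[j]
    }
    for (j in seq_len(units)) {
      az <- az + params$U_z[i, j] * h_prev[j]
      ar <- ar + params$U_r[i, j] * h_prev[j]
    }
    z[i] <- sig(az); r[i] <- sig(ar)
  }
  for (i in seq_len(units)) {
    am <- params$b_h[i]
    for (j in seq_len(d)) am <- am + params$W_h[i, j] * x_t[j]
    for (j in seq_len(units)) am <- am + params$U_h[i, j] * (r[j] * h_prev[j])
    m <- tanh(am)
    h_t[i] <- (1 - z[i]) * h_prev[i] + z[i] * m
  }
  h_t
}

random_gru_params <- function(units, d) {
  p <- list(
    W_z = matrix(rnorm(units * d), units, d),
    U_z = matrix(rnorm(units * units), units, units),
    b_z = rnorm(units),
    W_r = matrix(rnorm(units * d), units, d),
    U_r = matrix(rnorm(units * units), units, units),
    b_r = rnorm(units),
    W_h = matrix(rnorm(units * d), units, d),
    U_h = matrix(rnorm(units * units), units, units),
    b_h = rnorm(units)
  )
  structure(p, class = "gru_params", units = units, input_dim = d)
}

# AUC by exhaustive pos/neg pair comparison, ties counted 1/2.
auc_brute <- function(scores, labels) {
  sp <- scores[labels == 1]
  sn <- scores[labels == 0]
  tot <- 0
  for (a in sp) for (b in sn) {
    tot <- tot + (a > b) + 0.5 * (a == b)
  }
  tot / (length(sp) * length(sn))
}

# Average precision by an explicit threshold loop over the exact PR curve.
aps_brute <- function(scores, labels) {
  thr <- sort(unique(scores), decreasing = TRUE)
  n_pos <- sum(labels == 1)
  ap <- 0
  r_prev <- 0
  for (th in thr) {
    called <- scores >= th
    tp <- sum(called & labels == 1)
    prec <- tp / sum(called)
    rec <- tp / n_pos
    ap <- ap + (rec - r_prev) * prec
    r_prev <- rec
  }
  ap
}

# Small labelled dataset of random fixed-length sequences.
toy_dataset <- function(n = 20, L = 30, seed = 1) {
  withr::with_seed(seed, {
    tibble::tibble(
      id = sprintf("r%03d", seq_len(n)),
      sequence = vapply(seq_len(n), function(i) {
        paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
      }, character(1)),
      label = rep_len(c(0L, 1L), n)
    )
  })
}

dinuc_counts <- function(sequence) {
  s <- strsplit(sequence, "")[[1]]
  table(factor(paste0(s[-length(s)], s[-1]),
               levels = as.vector(outer(c("A", "C", "G", "T"),
                                        c("A", "C", "G", "T"), paste0))))
}
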