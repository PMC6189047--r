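#' Initialise the parameters of one GRU direction
#'
#' Nine tensors: input transforms `W_z, W_r, W_h` (`units x input_dim`,
#' uniform Glorot initialisation), recurrent transforms `U_z, U_r, U_h`
#' (`units x units`, orthogonal initialisation), and biases
#' `b_z, b_r, b_h` (zeros). Seeded for reproducibility.
#'
#' @param units Hidden state size.
#' @param input_dim Dimension of the per-step input vectors.
#' @param seed Integer seed.
#' @return A `gru_params` object (named list of the nine tensors).
#' @export
gru_params <- function(units, input_dim, seed = 1L) {
  units <- as.integer(units)
  input_dim <- as.integer(input_dim)
  stopifnot(units >= 1, input_dim >= 1)
  with_seed(seed, {
    lim <- sqrt(6 / (units + input_dim))
    glorot <- function() matrix(runif(units * input_dim, -lim, lim),
                                nrow = units, ncol = input_dim)
    ortho <- function() {
      a <- matrix(stats::rnorm(units * units), units, units)
      qr.Q(qr(a))
    }
    structure(
      list(
        W_z = glorot(), U_z = ortho(), b_z = numeric(units),
        W_r = glorot(), U_r = ortho(), b_r = numeric(units),
        W_h = glorot(), U_h = ortho(), b_h = numeric(units)
      ),
      class = "gru_params", units = units, input_dim = input_dim
    )
  })
}

#' One GRU recurrence step
#'
#' Computes, with `*` the element-wise product:
#' \deqn{z_t = \sigma(W_z x_t + U_z h_{t-1} + b_z)}
#' \deqn{r_t = \sigma(W_r x_t + U_r h_{t-1} + b_r)}
#' \deqn{m_t = \tanh(W_h x_t + U_h (r_t * h_{t-1}) + b_h)}
#' \deqn{h_t = (1 - z_t) * h_{t-1} + z_t * m_t}
#' Note the reset gate is applied to `h_{t-1}` *before* the recurrent
#' matrix multiplication; gate variants that apply it after do not satisfy
#' these equations.
#'
#' @param x_t Input vector of length `input_dim`.
#' @param h_prev Previous hidden state, length `units`.
#' @param params A `gru_params` object.
#' @return The new hidden state `h_t`, length `units`.
#' @examples
#' p <- gru_params(units = 3, input_dim = 2)
#' for (nm in names(p)) p[[nm]][] <- 0
#' gru_step(c(1, 1), c(0.4, -0.2, 0), p)  # 0.5 * h_prev
#' @export
gru_step <- function(x_t, h_prev, params) {
  stopifnot(inherits(params, "gru_params"))
  units <- attr(params, "units")
  input_dim <- attr(params, "input_dim")
  if (length(x_t) != input_dim || length(h_prev) != units) {
    abort("gru_step: shape mismatch between inputs and parameters")
  }
  if (!all(is.finite(x_t)) || !all(is.finite(h_prev))) {
    abort("gru_step: non-finite input")
  }
  z <- sigmoid(drop(params$W_z %*% x_t + params$U_z %*% h_prev) + params$b_z)
  r <- sigmoid(drop(params$W_r %*% x_t + params$U_r %*% h_prev) + params$b_r)
  m <- tanh(drop(params$W_h %*% x_t + params$U_h %*% (r * h_prev)) + params$b_h)
  (1 - z) * h_prev + z * m
}

# ---- batched internals -----------------------------------------------------
# X is a list over time of B x input_dim matrices; H, gates are B x units.
# mask columns are 0/1; a masked step leaves the hidden state unchanged.

add_bias <- function(M, b) M + rep(b, each = nrow(M))

gru_dir_forward <- function(params, Xseq, mask, keep_cache = FALSE) {
  B <- nrow(Xseq[[1]])
  units <- attr(params, "units")
  H <- matrix(0, B, units)
  Tn <- length(Xseq)
  states <- vector("list", Tn)
  cache <- if (keep_cache) vector("list", Tn) else NULL
  for (t in seq_len(Tn)) {
    X <- Xseq[[t]]
    z <- sigmoid(add_bias(tcrossprod(X, params$W_z) + tcrossprod(H, params$U_z),
                          params$b_z))
    r <- sigmoid(add_bias(tcrossprod(X, params$W_r) + tcrossprod(H, params$U_r),
                          params$b_r))
    rh <- r * H
    m <- tanh(add_bias(tcrossprod(X, params$W_h) + tcrossprod(rh, params$U_h),
                       params$b_h))
    h_new <- (1 - z) * H + z * m
    msk <- mask[, t]
    h_next <- H + msk * (h_new - H)
    if (keep_cache) cache[[t]] <- list(z = z, r = r, m = m, h_prev = H, msk = msk)
    H <- h_next
    states[[t]] <- H
  }
  list(h_final = H, states = states, cache = cache)
}

# Backward pass of one direction. d_states: list over time of gradients
# w.r.t. the *stored* state at each step (from pooling / next layer), may be
# NULL entries; d_final: gradient w.r.t. the final state. Returns gradients
# for the nine tensors and for each input X_t.
gru_dir_backward <- function(params, Xseq, fwd, d_states, d_final) {
  Tn <- length(Xseq)
  B <- nrow(Xseq[[1]])
  units <- attr(params, "units")
  g <- lapply(unclass(params), function(p) p * 0)
  dX <- vector("list", Tn)
  dH <- d_final
  for (t in rev(seq_len(Tn))) {
    if (!is.null(d_states[[t]])) dH <- dH + d_states[[t]]
    cc <- fwd$cache[[t]]
    msk <- cc$msk
    dh_new <- dH * msk
    dH_pass <- dH * (1 - msk)
    z <- cc$z; r <- cc$r; m <- cc$m; h_prev <- cc$h_prev
    # h_new = (1 - z) h_prev + z m
    dz <- dh_new * (m - h_prev)
    dm <- dh_new * z
    dh_prev <- dh_new * (1 - z)
    # m = tanh(W_h x + U_h (r h_prev) + b_h)
    da_m <- dm * (1 - m * m)
    g$W_h <- g$W_h + crossprod(da_m, Xseq[[t]])
    g$U_h <- g$U_h + crossprod(da_m, r * h_prev)
    g$b_h <- g$b_h + colSums(da_m)
    dX_t <- da_m %*% params$W_h
    drh <- da_m %*% params$U_h
    dr <- drh * h_prev
    dh_prev <- dh_prev + drh * r
    # gates
    da_z <- dz * z * (1 - z)
    da_r <- dr * r * (1 - r)
    g$W_z <- g$W_z + crossprod(da_z, Xseq[[t]])
    g$U_z <- g$U_z + crossprod(da_z, h_prev)
    g$b_z <- g$b_z + colSums(da_z)
    g$W_r <- g$W_r + crossprod(da_r, Xseq[[t]])
    g$U_r <- g$U_r + crossprod(da_r, h_prev)
    g$b_r <- g$b_r + colSums(da_r)
    dX_t <- dX_t + da_z %*% params$W_z + da_r %*% params$W_r
    dh_prev <- dh_prev + da_z %*% params$U_z + da_r %*% params$U_r
    dX[[t]] <- dX_t
    dH <- dH_pass + dh_prev
  }
  list(grads = g, dX = dX)
}

merge_states <- function(fout, bout, merge_mode) {
  switch(merge_mode,
    concatenate = cbind(fout, bout),
    sum = fout + bout,
    average = (fout + bout) / 2,
    multiplication = fout * bout,
    abort(paste0("unknown merge mode: ", merge_mode))
  )
}

merge_backward <- function(g, fout, bout, merge_mode, units) {
  switch(merge_mode,
    concatenate = list(df = g[, seq_len(units), drop = FALSE],
                       db = g[, units + seq_len(units), drop = FALSE]),
    sum = list(df = g, db = g),
    average = list(df = g / 2, db = g / 2),
    multiplication = list(df = g * bout, db = g * fout)
  )
}
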