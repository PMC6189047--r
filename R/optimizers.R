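# Mini-batch gradient-descent optimizers over a flat named list of
# parameter arrays. Each returns a stateful stepper; state lives in the
# closure, keyed by parameter name.

optimizer_default_lr <- c(
  SGD = 0.01, Adam = 0.001, Adagrad = 0.01, RMSprop = 0.001
)

make_optimizer <- function(name = c("Adam", "SGD", "Adagrad", "RMSprop"),
                           learning_rate = NULL) {
  name <- match.arg(name)
  lr <- learning_rate %||% optimizer_default_lr[[name]]
  state <- new.env(parent = emptyenv())
  eps <- 1e-8
  step_fn <- switch(name,
    SGD = function(params, grads) {
      for (nm in names(grads)) params[[nm]] <- params[[nm]] - lr * grads[[nm]]
      params
    },
    Adam = {
      beta1 <- 0.9; beta2 <- 0.999
      state$t <- 0
      function(params, grads) {
        state$t <- state$t + 1
        bc1 <- 1 - beta1^state$t
        bc2 <- 1 - beta2^state$t
        for (nm in names(grads)) {
          g <- grads[[nm]]
          m <- if (is.null(state[[paste0("m_", nm)]])) g * 0 else state[[paste0("m_", nm)]]
          v <- if (is.null(state[[paste0("v_", nm)]])) g * 0 else state[[paste0("v_", nm)]]
          m <- beta1 * m + (1 - beta1) * g
          v <- beta2 * v + (1 - beta2) * g * g
          state[[paste0("m_", nm)]] <- m
          state[[paste0("v_", nm)]] <- v
          params[[nm]] <- params[[nm]] - lr * (m / bc1) / (sqrt(v / bc2) + eps)
        }
        params
      }
    },
    Adagrad = function(params, grads) {
      for (nm in names(grads)) {
        g <- grads[[nm]]
        G <- if (is.null(state[[nm]])) g * 0 else state[[nm]]
        G <- G + g * g
        state[[nm]] <- G
        params[[nm]] <- params[[nm]] - lr * g / (sqrt(G) + eps)
      }
      params
    },
    RMSprop = {
      rho <- 0.9
      function(params, grads) {
        for (nm in names(grads)) {
          g <- grads[[nm]]
          G <- if (is.null(state[[nm]])) g * 0 else state[[nm]]
          G <- rho * G + (1 - rho) * g * g
          state[[nm]] <- G
          params[[nm]] <- params[[nm]] - lr * g / (sqrt(G) + eps)
        }
        params
      }
    }
  )
  list(name = name, learning_rate = lr, step = step_fn)
}
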