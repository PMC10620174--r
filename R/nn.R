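# Minimal dense-network machinery used by the dual adversarial
# deconfounding autoencoder: rectifier MLPs with a linear output layer,
# reverse-mode gradients, and Adam updates. Kept internal; the network is
# small enough (tens of thousands of parameters) that vectorised base R
# matrix products are adequate on one CPU.

mlp_init <- function(widths) {
  layers <- vector("list", length(widths) - 1)
  for (l in seq_along(layers)) {
    fan_in <- widths[l]
    layers[[l]] <- list(
      W = matrix(stats::rnorm(fan_in * widths[l + 1], sd = sqrt(2 / fan_in)),
                 fan_in, widths[l + 1]),
      b = numeric(widths[l + 1]))
  }
  layers
}

mlp_widths <- function(layers) {
  c(nrow(layers[[1]]$W), vapply(layers, function(l) ncol(l$W), 0L))
}

# forward pass; hidden activations are ReLU, the final layer is linear
# (decoder output or classification logits)
mlp_forward <- function(layers, x) {
  h <- vector("list", length(layers) + 1)
  h[[1]] <- x
  n_l <- length(layers)
  for (l in seq_len(n_l)) {
    z <- h[[l]] %*% layers[[l]]$W
    z <- sweep(z, 2, layers[[l]]$b, "+")
    h[[l + 1]] <- if (l < n_l) pmax(z, 0) else z
  }
  h
}

# reverse pass from the gradient at the (linear) output; returns per-layer
# gradients and the gradient at the input (needed to push adversary
# gradients through the embedding into the encoder)
mlp_backward <- function(layers, h, d_out) {
  n_l <- length(layers)
  grads <- vector("list", n_l)
  d <- d_out
  for (l in rev(seq_len(n_l))) {
    if (l < n_l) d <- d * (h[[l + 1]] > 0)
    gw <- crossprod(h[[l]], d)
    dimnames(gw) <- NULL
    grads[[l]] <- list(W = gw, b = unname(colSums(d)))
    d <- tcrossprod(d, layers[[l]]$W)
  }
  list(grads = grads, d_input = d)
}

adam_init <- function(layers) {
  list(t = 0L,
       m = lapply(layers, function(l) list(W = l$W * 0, b = l$b * 0)),
       v = lapply(layers, function(l) list(W = l$W * 0, b = l$b * 0)))
}

adam_step <- function(layers, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  c1 <- 1 - beta1^state$t
  c2 <- 1 - beta2^state$t
  for (l in seq_along(layers)) {
    for (p in c("W", "b")) {
      g <- grads[[l]][[p]]
      state$m[[l]][[p]] <- beta1 * state$m[[l]][[p]] + (1 - beta1) * g
      state$v[[l]][[p]] <- beta2 * state$v[[l]][[p]] + (1 - beta2) * g^2
      layers[[l]][[p]] <- layers[[l]][[p]] -
        lr * (state$m[[l]][[p]] / c1) / (sqrt(state$v[[l]][[p]] / c2) + eps)
    }
  }
  list(layers = layers, state = state)
}

# numerically stable softmax cross-entropy; y is a 0/1 indicator matrix.
# Returns the mean loss and the gradient at the logits.
softmax_ce <- function(logits, y) {
  z <- logits - apply(logits, 1, max)
  ez <- exp(z)
  p <- ez / rowSums(ez)
  loss <- -mean(rowSums(y * (z - log(rowSums(ez)))))
  list(loss = loss, grad = (p - y) / nrow(y), prob = p)
}

one_hot <- function(f) {
  f <- as.factor(f)
  y <- matrix(0, length(f), nlevels(f), dimnames = list(NULL, levels(f)))
  y[cbind(seq_along(f), as.integer(f))] <- 1
  y
}

nn_last <- function(h) h[[length(h)]]
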