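# Dense feed-forward network with tanh hidden layers and a sigmoid output,
# trained by mini-batch Nadam (Adam with Nesterov momentum) on binary
# cross-entropy with L2 penalties on both weights and biases. This is the
# compact classifier the pipeline trains on integrated feature vectors;
# it is small enough (1029 -> 64 -> 32 -> 1 at most) that plain BLAS-backed
# matrix code is fast.

.sigmoid <- function(z) 1 / (1 + exp(-z))

.mlpInit <- function(input_dim, hidden_sizes, init_sd) {
  dims <- c(input_dim, hidden_sizes, 1L)
  layers <- vector("list", length(dims) - 1L)
  for (i in seq_along(layers)) {
    # zero-mean Gaussian kernel initialization at a small fixed scale; zero bias
    layers[[i]] <- list(
      W = matrix(stats::rnorm(dims[i] * dims[i + 1L], 0, init_sd),
                 dims[i], dims[i + 1L]),
      b = numeric(dims[i + 1L]))
  }
  layers
}

.mlpForward <- function(layers, X) {
  activations <- vector("list", length(layers) + 1L)
  activations[[1L]] <- X
  n_layer <- length(layers)
  for (i in seq_len(n_layer)) {
    z <- sweep(activations[[i]] %*% layers[[i]]$W, 2L, layers[[i]]$b, "+")
    activations[[i + 1L]] <- if (i < n_layer) tanh(z) else .sigmoid(z)
  }
  activations
}

.mlpPredict <- function(layers, X) {
  as.numeric(.mlpForward(layers, X)[[length(layers) + 1L]])
}

.bceLoss <- function(p, y, layers, l2) {
  eps <- 1e-12
  p <- pmin(pmax(p, eps), 1 - eps)
  bce <- -mean(y * log(p) + (1 - y) * log(1 - p))
  penalty <- l2 * sum(vapply(layers, function(l) sum(l$W^2) + sum(l$b^2), 0))
  bce + penalty
}

# One gradient evaluation on a mini-batch. With sigmoid + BCE the output-layer
# delta collapses to (p - y) / n; tanh' = 1 - a^2 for the hidden layers.
.mlpGradients <- function(layers, X, y, l2) {
  acts <- .mlpForward(layers, X)
  n_layer <- length(layers)
  n <- nrow(X)
  grads <- vector("list", n_layer)
  delta <- (acts[[n_layer + 1L]] - y) / n
  for (i in rev(seq_len(n_layer))) {
    grads[[i]] <- list(
      W = crossprod(acts[[i]], delta) + 2 * l2 * layers[[i]]$W,
      b = colSums(delta) + 2 * l2 * layers[[i]]$b)
    if (i > 1L) {
      delta <- (delta %*% t(layers[[i]]$W)) * (1 - acts[[i]]^2)
    }
  }
  grads
}

.mlpTrain <- function(X, y, hidden_sizes, epochs, batch_size, learning_rate,
                      l2, init_sd, beta1 = 0.9, beta2 = 0.999, eps = 1e-7) {
  # Center the inputs (equivalent reparameterization, absorbable into the
  # first-layer biases). Min-max-scaled features are all non-negative, so
  # without centering every weight gradient of a hidden unit shares the sign
  # of that unit's delta, and the adaptive optimizer's sign-normalized steps
  # move all of a unit's weights coherently — a large common-mode random walk
  # that saturates tanh. Centering decorrelates the per-weight gradient signs.
  center <- colMeans(X)
  X <- sweep(X, 2L, center, "-")
  layers <- .mlpInit(ncol(X), hidden_sizes, init_sd)
  m <- lapply(layers, function(l) list(W = l$W * 0, b = l$b * 0))
  v <- lapply(layers, function(l) list(W = l$W * 0, b = l$b * 0))
  n <- nrow(X)
  step <- 0L
  loss_history <- numeric(epochs)
  for (epoch in seq_len(epochs)) {
    order_idx <- sample.int(n)
    starts <- seq(1L, n, by = batch_size)
    for (s in starts) {
      idx <- order_idx[s:min(s + batch_size - 1L, n)]
      g <- .mlpGradients(layers, X[idx, , drop = FALSE], y[idx], l2)
      step <- step + 1L
      bc1 <- 1 - beta1^step
      bc2 <- 1 - beta2^step
      for (i in seq_along(layers)) {
        for (p in c("W", "b")) {
          m[[i]][[p]] <- beta1 * m[[i]][[p]] + (1 - beta1) * g[[i]][[p]]
          v[[i]][[p]] <- beta2 * v[[i]][[p]] + (1 - beta2) * g[[i]][[p]]^2
          # Nesterov-accelerated Adam: blend the bias-corrected first moment
          # with the bias-corrected current gradient
          m_bar <- beta1 * (m[[i]][[p]] / bc1) + (1 - beta1) * g[[i]][[p]] / bc1
          layers[[i]][[p]] <- layers[[i]][[p]] -
            learning_rate * m_bar / (sqrt(v[[i]][[p]] / bc2) + eps)
        }
      }
    }
    loss_history[epoch] <- .bceLoss(.mlpPredict(layers, X), y, layers, l2)
  }
  list(layers = layers, center = center, loss_history = loss_history)
}
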