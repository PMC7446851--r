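# Small fully-connected regression network: sigmoid hidden layers, a single
# leaky-ReLU output unit, inverted dropout on the hidden activations, Adam on
# minibatch mean-squared error. Sized for the feature vectors produced here
# (hundreds of samples, low-hundreds of features), dense matrix ops only.

.leaky <- function(z, slope = 0.01) ifelse(z > 0, z, slope * z)
.leaky_grad <- function(z, slope = 0.01) ifelse(z > 0, 1, slope)
.sigmoid <- function(z) 1 / (1 + exp(-z))

.mlp_init <- function(p, layers, nodes) {
  sizes <- c(p, rep(nodes, layers), 1L)
  W <- list(); b <- list()
  for (l in seq_len(length(sizes) - 1L)) {
    fan_in <- sizes[l]
    W[[l]] <- matrix(stats::rnorm(fan_in * sizes[l + 1L],
                                  sd = sqrt(1 / fan_in)),
                     nrow = fan_in)
    b[[l]] <- rep(0, sizes[l + 1L])
  }
  list(W = W, b = b)
}

.mlp_forward <- function(net, X, dropout = 0, training = FALSE) {
  L <- length(net$W)
  A <- list(X)         # activations entering each layer
  Z <- list()
  masks <- list()
  for (l in seq_len(L)) {
    Z[[l]] <- sweep(A[[l]] %*% net$W[[l]], 2, net$b[[l]], "+")
    if (l < L) {
      h <- .sigmoid(Z[[l]])
      if (training && dropout > 0) {
        m <- matrix(stats::rbinom(length(h), 1L, 1 - dropout) /
                      (1 - dropout), nrow = nrow(h))
        h <- h * m
        masks[[l]] <- m
      }
      A[[l + 1L]] <- h
    } else {
      A[[l + 1L]] <- .leaky(Z[[l]])
    }
  }
  list(A = A, Z = Z, masks = masks, yhat = A[[L + 1L]][, 1L])
}

.mlp_train <- function(X, y, layers, nodes, dropout, epochs,
                       batch_size = 32L, lr = 1e-3, seed = 1L) {
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  })
  set.seed(seed)
  n <- nrow(X); p <- ncol(X)
  net <- .mlp_init(p, layers, nodes)
  L <- length(net$W)
  # Adam state
  mW <- lapply(net$W, function(w) w * 0); vW <- mW
  mb <- lapply(net$b, function(b) b * 0); vb <- mb
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8; t <- 0
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    for (start in seq(1L, n, by = batch_size)) {
      idx <- ord[start:min(start + batch_size - 1L, n)]
      fw <- .mlp_forward(net, X[idx, , drop = FALSE], dropout,
                         training = TRUE)
      m <- length(idx)
      # dL/dyhat for mean squared error
      delta <- matrix(2 * (fw$yhat - y[idx]) / m, ncol = 1L) *
        .leaky_grad(fw$Z[[L]])
      for (l in rev(seq_len(L))) {
        gW <- crossprod(fw$A[[l]], delta)
        gb <- colSums(delta)
        if (l > 1L) {
          back <- delta %*% t(net$W[[l]])
          h <- .sigmoid(fw$Z[[l - 1L]])
          grad_h <- h * (1 - h)
          if (dropout > 0 && length(fw$masks) >= l - 1L &&
              !is.null(fw$masks[[l - 1L]]))
            back <- back * fw$masks[[l - 1L]]
          delta <- back * grad_h
        }
        t_l <- t + 1
        mW[[l]] <- beta1 * mW[[l]] + (1 - beta1) * gW
        vW[[l]] <- beta2 * vW[[l]] + (1 - beta2) * gW^2
        mb[[l]] <- beta1 * mb[[l]] + (1 - beta1) * gb
        vb[[l]] <- beta2 * vb[[l]] + (1 - beta2) * gb^2
        mhW <- mW[[l]] / (1 - beta1^t_l); vhW <- vW[[l]] / (1 - beta2^t_l)
        mhb <- mb[[l]] / (1 - beta1^t_l); vhb <- vb[[l]] / (1 - beta2^t_l)
        net$W[[l]] <- net$W[[l]] - lr * mhW / (sqrt(vhW) + eps)
        net$b[[l]] <- net$b[[l]] - lr * mhb / (sqrt(vhb) + eps)
      }
      t <- t + 1
    }
  }
  net
}

.mlp_predict <- function(net, X) {
  .mlp_forward(net, X, dropout = 0, training = FALSE)$yhat
}
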