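# Exact t-SNE on a precomputed distance matrix. No CRAN t-SNE
# implementation is available in this package's dependency set, so the
# standard algorithm (Gaussian input kernel calibrated to a target
# perplexity by bisection, Student-t output kernel, gradient descent with
# momentum and early exaggeration) is implemented here directly. The O(n^2)
# exact formulation is appropriate for the corpus sizes this package
# handles (hundreds of compounds).

# Row-wise conditional probabilities at the precision that hits the target
# perplexity; standard bisection on log-precision.
tsne_input_probs <- function(D, perplexity) {
  n <- nrow(D)
  target <- log(perplexity)
  P <- matrix(0, n, n)
  D2 <- D^2
  for (i in seq_len(n)) {
    di <- D2[i, -i]
    lo <- -Inf; hi <- Inf; beta <- 1
    for (iter in 1:50) {
      w <- exp(-di * beta)
      sw <- sum(w)
      if (sw <= 0) { h <- 0 } else {
        p <- w / sw
        h <- -sum(p[p > 0] * log(p[p > 0]))
      }
      if (abs(h - target) < 1e-5) break
      if (h > target) { lo <- beta; beta <- if (is.finite(hi)) (beta + hi) / 2 else beta * 2 }
      else { hi <- beta; beta <- if (is.finite(lo)) (beta + lo) / 2 else beta / 2 }
    }
    w <- exp(-di * beta)
    P[i, -i] <- if (sum(w) > 0) w / sum(w) else 1 / (n - 1)
  }
  P <- (P + t(P)) / (2 * n)
  pmax(P, 1e-12)
}

# Exact t-SNE; returns 2D coordinates and the final KL divergence.
tsne_embed <- function(D, perplexity = 30, max_iter = 500L, seed = 42L,
                       learning_rate = 100) {
  stopifnot(is.matrix(D), nrow(D) == ncol(D))
  n <- nrow(D)
  perplexity <- min(perplexity, (n - 1) / 3)
  P <- tsne_input_probs(D, perplexity)
  withr::with_seed(seed, {
    Y <- matrix(stats::rnorm(n * 2, sd = 1e-4), n, 2)
  })
  inc <- matrix(0, n, 2)
  exaggeration <- 12
  stop_exag <- min(250L, max_iter %/% 2L)
  kl <- NA_real_
  for (iter in seq_len(max_iter)) {
    Pe <- if (iter <= stop_exag) P * exaggeration else P
    sumY <- rowSums(Y^2)
    num <- 1 / (1 + outer(sumY, sumY, "+") - 2 * tcrossprod(Y))
    diag(num) <- 0
    Q <- pmax(num / sum(num), 1e-12)
    L <- (Pe - Q) * num
    grad <- 4 * (diag(rowSums(L)) - L) %*% Y
    momentum <- if (iter < 20) 0.5 else 0.8
    inc <- momentum * inc - learning_rate * grad
    Y <- Y + inc
    Y <- sweep(Y, 2, colMeans(Y))
  }
  sumY <- rowSums(Y^2)
  num <- 1 / (1 + outer(sumY, sumY, "+") - 2 * tcrossprod(Y))
  diag(num) <- 0
  Q <- pmax(num / sum(num), 1e-12)
  kl <- sum(P * log(P / Q))
  list(coords = Y, kl = kl)
}
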