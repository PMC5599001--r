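# Independent brute-force oracles used to validate the vectorized
# implementations. Deliberately written as plain loops over pixels,
# descriptors and components.

# per-pixel / per-bin SIFT histogram accumulation at one patch center
oracle_sift_descriptor <- function(px, center, bin_size) {
  b <- bin_size
  r0 <- center[1]; c0 <- center[2]
  offs <- (1:4 - 2.5) * b
  acc <- array(0, c(4, 4, 8))
  for (p in (r0 - 2 * b + 1):(r0 + 2 * b - 1)) {
    for (q in (c0 - 2 * b + 1):(c0 + 2 * b - 1)) {
      gx <- (px[p + 1, q + 2] - px[p + 1, q]) / 2       # 0-based (p, q)
      gy <- (px[p + 2, q + 1] - px[p, q + 1]) / 2
      mag <- sqrt(gx^2 + gy^2)
      ang <- atan2(gy, gx) %% (2 * pi)
      o <- ang / (pi / 4)
      o0 <- floor(o); whi <- o - o0
      i0 <- (o0 %% 8) + 1; i1 <- ((o0 + 1) %% 8) + 1
      for (a in 1:4) {
        wr <- max(0, 1 - abs(p - (r0 + offs[a])) / b)
        if (wr == 0) next
        for (bb in 1:4) {
          wc <- max(0, 1 - abs(q - (c0 + offs[bb])) / b)
          if (wc == 0) next
          acc[a, bb, i0] <- acc[a, bb, i0] + mag * (1 - whi) * wr * wc
          acc[a, bb, i1] <- acc[a, bb, i1] + mag * whi * wr * wc
        }
      }
    }
  }
  v <- numeric(128)
  for (a in 1:4) for (bb in 1:4) for (o in 1:8) {
    v[((a - 1) * 4 + (bb - 1)) * 8 + o] <- acc[a, bb, o]
  }
  n <- sqrt(sum(v^2))
  if (n < 1e-12) return(v * 0)
  v <- pmin(v / n, 0.2)
  v / sqrt(sum(v^2))
}

# naive per-descriptor / per-component double loop Fisher Vector
# (pre-normalization), including naive posterior computation
oracle_fisher_vector <- function(weights, means, variances, x) {
  K <- length(weights); d <- ncol(means); n <- nrow(x)
  G <- matrix(0, n, K)
  for (i in seq_len(n)) {
    p <- vapply(seq_len(K), function(k) {
      weights[k] * prod(stats::dnorm(x[i, ], means[k, ], sqrt(variances[k, ])))
    }, 0)
    G[i, ] <- p / sum(p)
  }
  first <- matrix(0, K, d); second <- matrix(0, K, d)
  for (k in seq_len(K)) {
    for (j in seq_len(d)) {
      first[k, j] <- sum(G[, k] * (x[, j] - means[k, j]) / sqrt(variances[k, j])) /
        (n * sqrt(weights[k]))
      second[k, j] <- sum(G[, k] * ((x[, j] - means[k, j])^2 / variances[k, j] - 1)) /
        (n * sqrt(2 * weights[k]))
    }
  }
  c(as.vector(t(first)), as.vector(t(second)))
}

# random diagonal GMM with well-conditioned parameters
random_gmm <- function(K, d, seed) {
  withr::with_seed(seed, {
    w <- stats::runif(K, 0.5, 2); w <- w / sum(w)
    structure(list(n_components = K, weights = w,
                   means = matrix(stats::rnorm(K * d, sd = 2), K, d),
                   variances = matrix(stats::runif(K * d, 0.3, 2), K, d)),
              class = "gmm_model")
  })
}

# 4-neighbour connected-component count of a binary matrix (BFS labelling)
oracle_component_count <- function(binary) {
  h <- nrow(binary); w <- ncol(binary)
  seen <- matrix(FALSE, h, w)
  count <- 0L
  for (i in seq_len(h)) for (j in seq_len(w)) {
    if (!binary[i, j] || seen[i, j]) next
    count <- count + 1L
    queue <- list(c(i, j)); seen[i, j] <- TRUE
    while (length(queue)) {
      p <- queue[[length(queue)]]; queue[[length(queue)]] <- NULL
      for (dd in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
        q <- p + dd
        if (q[1] >= 1 && q[1] <= h && q[2] >= 1 && q[2] <= w &&
            binary[q[1], q[2]] && !seen[q[1], q[2]]) {
          seen[q[1], q[2]] <- TRUE
          queue[[length(queue) + 1]] <- q
        }
      }
    }
  }
  count
}
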