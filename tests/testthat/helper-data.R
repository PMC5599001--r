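# small in-code fixtures shared across test files

noise_image <- function(h = 64, w = 64, seed = 1) {
  px <- withr::with_seed(seed, matrix(stats::runif(h * w), h, w))
  labeled_image(px, label = "noise")
}

# vertical step edge: dark left half, bright right half
step_edge_image <- function(h = 64, w = 64) {
  px <- matrix(0.2, h, w)
  px[, (w %/% 2 + 1):w] <- 0.8
  labeled_image(px, label = "edge")
}

# two well-separated Gaussian blobs in 2-D with labels
blob_data <- function(n_per = 30, seed = 1, sep = 8) {
  withr::with_seed(seed, {
    x <- rbind(matrix(stats::rnorm(2 * n_per), ncol = 2),
               matrix(stats::rnorm(2 * n_per, mean = sep), ncol = 2))
    list(x = x, y = rep(c("1.1", "2.1"), each = n_per))
  })
}

# concentric rings: not linearly separable
rings_data <- function(n_per = 60, seed = 1) {
  withr::with_seed(seed, {
    th <- stats::runif(2 * n_per, 0, 2 * pi)
    r <- c(stats::runif(n_per, 0, 0.9), stats::runif(n_per, 1.8, 2.6))
    list(x = cbind(r * cos(th), r * sin(th)),
         y = rep(c("1.1", "2.1"), each = n_per))
  })
}

xor_data <- function(n_per_quad = 40, seed = 1) {
  withr::with_seed(seed, {
    sgn <- as.matrix(expand.grid(c(-1, 1), c(-1, 1)))
    x <- do.call(rbind, lapply(seq_len(4), function(i) {
      cbind(stats::rnorm(n_per_quad, 2 * sgn[i, 1], 0.5),
            stats::rnorm(n_per_quad, 2 * sgn[i, 2], 0.5))
    }))
    y <- rep(c("1.1", "2.1", "2.1", "1.1"), each = n_per_quad)
    list(x = x, y = y)
  })
}

# tiny synthetic dataset written as PNGs under a temp dir
write_tiny_dataset <- function(dir, n_classes = 2, n_images = 3, seed = 1) {
  for (ci in seq_len(n_classes)) {
    cl <- sprintf("%d.1", ci)
    dir.create(file.path(dir, cl), recursive = TRUE, showWarnings = FALSE)
    for (i in seq_len(n_images)) {
      px <- withr::with_seed(seed + ci * 100 + i, matrix(stats::runif(32 * 32), 32, 32))
      png::writePNG(px, file.path(dir, cl, sprintf("img_%02d.png", i)))
    }
  }
  dir
}

fast_encoder_config <- function(...) {
  encoder_config(gmm_k = 4L, pca_dim = 16L, subsample = 5000L, ...)
}
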