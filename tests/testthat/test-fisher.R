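test_that("PCA recovers a 1-D subspace and preserves distances at full rank", {
  # points on a line in 3-D
  t <- withr::with_seed(1, rnorm(50))
  dir <- c(1, 2, -1) / sqrt(6)
  x <- outer(t, dir) + 5
  pca <- fit_pca(x, 1)
  expect_lt(abs(abs(sum(pca$basis[, 1] * dir)) - 1), 1e-8)
  recon <- apply_pca(pca, x) %*% t(pca$basis)
  expect_lt(max(abs(sweep(x, 2, pca$mean) - recon)), 1e-8)

  # full rank preserves pairwise distances
  y <- withr::with_seed(2, matrix(rnorm(40 * 5), 40, 5))
  proj <- apply_pca(fit_pca(y, 5), y)
  expect_lt(max(abs(dist(y) - dist(proj))), 1e-6)
  expect_error(fit_pca(y, 6), "exceeds")
})

test_that("PCA axis variances equal the covariance eigenvalues", {
  x <- withr::with_seed(3, matrix(rnorm(500 * 6), 500, 6) %*% diag(c(3, 2, 1.5, 1, 0.5, 0.2)))
  pca <- fit_pca(x, 3)
  ev <- eigen(stats::cov(x), symmetric = TRUE)$values[1:3]
  proj_var <- apply(apply_pca(pca, x), 2, stats::var)
  expect_lt(max(abs(proj_var - ev)), 1e-8)
  expect_lt(max(abs(crossprod(pca$basis) - diag(3))), 1e-6)
})

test_that("K = 1 EM reduces to the closed-form mean and (1/N) variance", {
  x <- withr::with_seed(4, matrix(rnorm(200 * 3, mean = 2, sd = 1.5), 200, 3))
  g <- fit_gmm(x, K = 1, seed = 1)
  expect_lt(max(abs(g$means[1, ] - colMeans(x))), 1e-8)
  mle_var <- colMeans(sweep(x, 2, colMeans(x))^2)
  expect_lt(max(abs(g$variances[1, ] - mle_var)), 1e-8)
})

test_that("EM recovers well-separated mixture components", {
  centers <- rbind(c(0, 0), c(12, 0), c(0, 12))  # separation 12 sigma
  x <- withr::with_seed(5, {
    comp <- sample(1:3, 3000, replace = TRUE)
    centers[comp, ] + matrix(rnorm(6000), ncol = 2)
  })
  g <- fit_gmm(x, K = 3, seed = 6)
  perms <- list(1:3, c(1, 3, 2), c(2, 1, 3), c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  err <- min(vapply(perms, function(p) max(abs(g$means[p, ] - centers)), 0))
  expect_lt(err, 0.1)
  expect_true(all(g$weights > 0))
  expect_lt(abs(sum(g$weights) - 1), 1e-8)
})

test_that("EM log-likelihood is non-decreasing and seeded fits are identical", {
  x <- withr::with_seed(7, rbind(matrix(rnorm(400), ncol = 2),
                                 matrix(rnorm(400, mean = 3), ncol = 2)))
  g1 <- fit_gmm(x, K = 3, seed = 11)
  expect_true(all(diff(g1$loglik) >= -1e-9))
  g2 <- fit_gmm(x, K = 3, seed = 11)
  expect_identical(g1$means, g2$means)
  expect_identical(g1$variances, g2$variances)
  expect_error(fit_gmm(x[1:20, ], K = 3), "at least")
})

test_that("EM agrees with an independent diagonal-GMM implementation", {
  skip_if_not_installed("mclust")
  withr::local_package("mclust")
  x <- withr::with_seed(8, rbind(matrix(rnorm(600, sd = 0.7), ncol = 2),
                                 matrix(rnorm(600, mean = 5, sd = 0.7), ncol = 2)))
  g <- fit_gmm(x, K = 2, seed = 2)
  mc <- Mclust(x, G = 2, modelNames = "VVI", verbose = FALSE)
  ours <- g$means[order(g$means[, 1]), ]
  theirs <- t(mc$parameters$mean)[order(t(mc$parameters$mean)[, 1]), ]
  expect_lt(max(abs(ours - theirs)), 0.05)
})

test_that("soft assignment is a normalized posterior", {
  g <- random_gmm(3, 4, seed = 9)
  x <- withr::with_seed(10, matrix(rnorm(50 * 4, sd = 3), 50, 4))
  gam <- soft_assign(g, x)
  expect_true(all(abs(rowSums(gam) - 1) < 1e-10))
  expect_true(all(gam >= 0))
  # single-component model: posterior 1
  g1 <- random_gmm(1, 4, seed = 11)
  expect_equal(soft_assign(g1, rnorm(4)), 1)
  # descriptor at a well-separated component mean: posterior > 0.99
  gs <- structure(list(n_components = 3, weights = rep(1 / 3, 3),
                       means = rbind(c(0, 0), c(20, 0), c(0, 20)),
                       variances = matrix(1, 3, 2)), class = "gmm_model")
  expect_gt(soft_assign(gs, c(20, 0))[2], 0.99)
  # density-ratio oracle for a generic point
  g2 <- random_gmm(2, 3, seed = 12)
  pt <- c(0.5, -1, 2)
  dens <- vapply(1:2, function(k) {
    g2$weights[k] * prod(dnorm(pt, g2$means[k, ], sqrt(g2$variances[k, ])))
  }, 0)
  expect_lt(max(abs(soft_assign(g2, pt) - dens / sum(dens))), 1e-12)
})

test_that("the Fisher Vector equals the naive double-loop oracle", {
  for (case in 1:20) {
    cfg <- withr::with_seed(100 + case, list(
      K = sample(1:4, 1), d = sample(c(2, 5, 16), 1), n = sample(c(10, 80, 200), 1)))
    g <- random_gmm(cfg$K, cfg$d, seed = 200 + case)
    x <- withr::with_seed(300 + case, matrix(rnorm(cfg$n * cfg$d, sd = 2), cfg$n, cfg$d))
    fv <- encode_fv(g, x, normalization = "none", posterior_floor = 0)
    oracle <- oracle_fisher_vector(g$weights, g$means, g$variances, x)
    expect_length(fv$values, 2 * cfg$K * cfg$d)
    expect_lt(max(abs(fv$values - oracle)), 1e-8)
  }
})

test_that("FV has length 2*K*d and a unit norm after ssr+l2 normalization", {
  g <- random_gmm(4, 16, seed = 13)
  x <- withr::with_seed(14, matrix(rnorm(100 * 16), 100, 16))
  fv <- encode_fv(g, x)
  expect_length(fv$values, 128)
  expect_lt(abs(sqrt(sum(fv$values^2)) - 1), 1e-6)
})

test_that("FV pooling is orderless and invariant to descriptor duplication", {
  g <- random_gmm(3, 6, seed = 15)
  x <- withr::with_seed(16, matrix(rnorm(60 * 6), 60, 6))
  fv <- encode_fv(g, x, normalization = "none", posterior_floor = 0)
  perm <- withr::with_seed(17, sample(60))
  fv_perm <- encode_fv(g, x[perm, ], normalization = "none", posterior_floor = 0)
  expect_lt(max(abs(fv$values - fv_perm$values)), 1e-12)
  fv_dup <- encode_fv(g, rbind(x, x), normalization = "none", posterior_floor = 0)
  expect_lt(max(abs(fv$values - fv_dup$values)), 1e-10)
})

test_that("a single descriptor under K = 1 gives the closed-form FV", {
  g <- structure(list(n_components = 1, weights = 1,
                      means = matrix(c(1, -2), 1), variances = matrix(c(4, 0.25), 1)),
                 class = "gmm_model")
  x <- matrix(c(3, -1), 1)
  fv <- encode_fv(g, x, normalization = "none", posterior_floor = 0)
  expected_first <- (x[1, ] - g$means[1, ]) / sqrt(g$variances[1, ])
  expected_second <- ((x[1, ] - g$means[1, ])^2 / g$variances[1, ] - 1) / sqrt(2)
  expect_lt(max(abs(fv$values - c(expected_first, expected_second))), 1e-10)
})

test_that("descriptors sampled from the model itself score near zero", {
  g <- random_gmm(3, 6, seed = 18)
  n <- 50000
  x <- sample_gmm(g, n, seed = 19)
  fv <- encode_fv(g, x, normalization = "none", posterior_floor = 0)
  # per-entry standard error from the per-descriptor score contributions
  gam <- soft_assign(g, x)
  se <- numeric(length(fv$values))
  idx <- 1
  for (k in 1:3) for (j in 1:6) {
    term <- gam[, k] * (x[, j] - g$means[k, j]) / sqrt(g$variances[k, j]) / sqrt(g$weights[k])
    se[idx] <- sd(term) / sqrt(n)
    idx <- idx + 1
  }
  for (k in 1:3) for (j in 1:6) {
    term <- gam[, k] * ((x[, j] - g$means[k, j])^2 / g$variances[k, j] - 1) /
      sqrt(2 * g$weights[k])
    se[idx] <- sd(term) / sqrt(n)
    idx <- idx + 1
  }
  expect_true(all(abs(fv$values) <= 3 * se))
})

test_that("FC pooling normalizes and concatenation follows the block scheme", {
  expect_equal(fc_pool(rep(0, 8))$values, rep(0, 8))
  v <- fc_pool(c(3, 4))$values
  expect_lt(abs(sqrt(sum(v^2)) - 1), 1e-12)
  e1 <- c(1, rep(0, 5))
  expect_equal(fc_pool(e1)$values, e1)

  a <- fc_pool(c(1, 0), tag = "FC-toy")
  b <- fc_pool(c(0, 2, 0), tag = "FV-toy")
  cc <- concat_representations(list(a, b))
  expect_length(cc$values, 5)
  expect_lt(abs(sqrt(sum(cc$values^2)) - 1), 1e-12)
  # two unit-norm parts each end up with block norm 1/sqrt(2)
  expect_lt(abs(sqrt(sum(cc$values[1:2]^2)) - 1 / sqrt(2)), 1e-12)
  expect_equal(cc$tag, "FC-toy & FV-toy")
  # three parts: dimensions add up
  c3 <- concat_representations(list(rnorm(4), rnorm(7), rnorm(2)))
  expect_length(c3$values, 13)
  # single part: identical to its normalized self
  single <- concat_representations(list(b))
  expect_equal(single$values, b$values / sqrt(sum(b$values^2)))
  expect_error(concat_representations(list()), "at least one")
})
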