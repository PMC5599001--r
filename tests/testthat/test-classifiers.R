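test_that("the one-vs-all linear SVM separates Gaussian blobs perfectly", {
  d <- blob_data(30, seed = 1)
  m <- train_original(d$x, d$y)
  expect_equal(predict(m, d$x), d$y)
  expect_length(m$state$models, 2)
})

test_that("one binary machine is trained per class", {
  withr::with_seed(2, {
    n_cl <- 7
    # class blobs on a circle: each is linearly separable from the rest
    x <- do.call(rbind, lapply(seq_len(n_cl), function(i) {
      th <- 2 * pi * i / n_cl
      cbind(rnorm(12, 10 * cos(th), 0.5), rnorm(12, 10 * sin(th), 0.5))
    }))
    y <- rep(sprintf("%d.1", seq_len(n_cl)), each = 12)
  })
  m <- train_original(x, y)
  expect_length(m$state$models, n_cl)
  expect_equal(m$classes, sprintf("%d.1", 1:7))
  expect_equal(predict(m, x), y)
})

test_that("duplicated points under two labels still predict via the tie rule", {
  x <- rbind(c(0, 0), c(0, 0), c(5, 5), c(5, 5))
  y <- c("1.1", "2.1", "1.1", "2.1")
  m <- train_original(x, y)
  p <- predict(m, rbind(c(0, 0), c(9, 9)))
  expect_length(p, 2)
  expect_true(all(p %in% c("1.1", "2.1")))
})

test_that("OvA and OvO linear SVMs agree on separated 3-class data", {
  withr::with_seed(3, {
    x <- rbind(matrix(rnorm(2 * 20), ncol = 2),
               matrix(rnorm(2 * 20, mean = 10), ncol = 2),
               cbind(rnorm(20, 10), rnorm(20, -10)))
    y <- rep(c("1.1", "2.1", "3.1"), each = 20)
  })
  ova <- train_original(x, y)
  ovo <- train_optimized(x, y, svm_spec("linear"), budget = 5, seed = 4)
  expect_equal(predict(ova, x), y)
  expect_equal(predict(ovo, x), y)
})

test_that("Bayes-optimized SVM is seeded, keeps the C = 1 incumbent, and hits CV 1 on separable data", {
  d <- blob_data(25, seed = 5)
  m1 <- train_optimized(d$x, d$y, svm_spec("linear"), budget = 8, seed = 6)
  m2 <- train_optimized(d$x, d$y, svm_spec("linear"), budget = 8, seed = 6)
  expect_identical(m1$config$best_params, m2$config$best_params)
  expect_equal(m1$config$cv_accuracy, 1.0)
  # the default C = 1 (log10 C = 0) is always in the trace, and the optimum
  # can never fall below its CV score
  expect_true(any(abs(m1$config$trace$x1) < 1e-9))
  default_cv <- m1$config$trace$value[abs(m1$config$trace$x1) < 1e-9][1]
  expect_gte(m1$config$cv_accuracy, default_cv)
})

test_that("an optimized RBF SVM beats an optimized linear SVM on rings", {
  d <- rings_data(50, seed = 7)
  lin <- train_optimized(d$x, d$y, svm_spec("linear"), budget = 6, seed = 8)
  rbf <- train_optimized(d$x, d$y, svm_spec("rbf"), budget = 10, seed = 8)
  expect_gt(rbf$config$cv_accuracy, lin$config$cv_accuracy)
  expect_gt(rbf$config$cv_accuracy, 0.9)
})

test_that("boosted trees fit separable data, are seeded, and solve XOR", {
  d <- blob_data(25, seed = 9)
  m <- train_boosted_trees(d$x, d$y, n_estimators = 30, seed = 10)
  expect_equal(predict(m, d$x), d$y)
  m2 <- train_boosted_trees(d$x, d$y, n_estimators = 30, seed = 10)
  expect_identical(predict(m, d$x), predict(m2, d$x))

  xo <- xor_data(40, seed = 11)
  test <- xor_data(40, seed = 12)
  mx <- train_boosted_trees(xo$x, xo$y, n_estimators = 100, max_depth = 2, seed = 13)
  expect_gt(mean(predict(mx, test$x) == test$y), 0.9)
})

test_that("predictions are row-order invariant and dimension-checked", {
  d <- blob_data(20, seed = 14)
  m <- train_original(d$x, d$y)
  perm <- withr::with_seed(15, sample(nrow(d$x)))
  expect_equal(predict(m, d$x[perm, ]), predict(m, d$x)[perm])
  expect_length(predict(m, d$x[1, , drop = FALSE]), 1)
  expect_error(predict(m, cbind(d$x, 1)), "dimension")
  expect_error(train_original(d$x, rep("1.1", nrow(d$x))), "two classes")
})
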