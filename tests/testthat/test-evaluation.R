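test_that("the confusion matrix follows the (true i, predicted j) convention", {
  classes <- c("1.1", "2.1", "3.1")
  truth <- rep(classes, each = 10)
  cm <- confusion_matrix(truth, truth, classes)
  expect_equal(diag(cm), setNames(rep(10L, 3), classes))
  expect_equal(sum(cm) - sum(diag(cm)), 0)

  cm1 <- confusion_matrix("1.1", "2.1", classes)
  expect_equal(cm1["1.1", "2.1"], 1L)
  expect_equal(sum(cm1), 1L)

  pred <- withr::with_seed(1, sample(classes, 30, replace = TRUE))
  cmr <- confusion_matrix(truth, pred, classes)
  expect_equal(rowSums(cmr), setNames(rep(10, 3), classes))
  expect_equal(sum(cmr), 30)
  # independent recount
  for (i in classes) for (j in classes) {
    expect_equal(unname(cmr[i, j]), sum(truth == i & pred == j))
  }
  expect_error(confusion_matrix("9.9", "1.1", classes), "unknown label")
})

test_that("per-class accuracy is the diagonal over the row sum", {
  cm <- matrix(c(8, 2, 1, 9), 2, byrow = TRUE,
               dimnames = list(c("1.1", "2.1"), c("1.1", "2.1")))
  expect_equal(per_class_accuracy(cm), c("1.1" = 0.8, "2.1" = 0.9))
  cm0 <- cm; cm0[2, ] <- 0
  expect_error(per_class_accuracy(cm0), "no observations")
  # agrees with accuracy of the class-restricted label lists
  truth <- c(rep("1.1", 10), rep("2.1", 10))
  pred <- c(rep("1.1", 8), rep("2.1", 2), rep("1.1", 1), rep("2.1", 9))
  cm2 <- confusion_matrix(truth, pred, c("1.1", "2.1"))
  expect_equal(unname(per_class_accuracy(cm2)["1.1"]),
               mean(pred[truth == "1.1"] == "1.1"))
})

test_that("an oracle classifier stub yields accuracy 1 and a diagonal confusion", {
  idx <- generate_dataset(get_preset("demo5"), images_per_class = 4,
                          size = c(64, 64), seed = 3)
  oracle <- classifier_config("custom",
                              train_fun = function(x, y, seed) NULL,
                              predict_fun = function(state, x, truth) truth)
  rep <- run_repeated_eval(idx, encoder_config(), oracle, recipe = "FC-toy",
                           repeats = 3, per_class_train = 2, seed = 4)
  expect_equal(rep$per_repeat_accuracies, rep(1, 3))
  expect_equal(rep$mean_accuracy, 1)
  expect_true(all(rep$confusion[upper.tri(rep$confusion)] == 0))
  expect_true(all(rep$confusion[lower.tri(rep$confusion)] == 0))
  expect_equal(unname(diag(rep$confusion)), rep(6L, 5))  # 3 repeats x 2 test
  # accumulated rows sum to repeats x per-class test count
  expect_equal(unname(rowSums(rep$confusion)), rep(6, 5))
  # overall accuracy = trace / total exactly
  expect_identical(sum(diag(rep$confusion)) / sum(rep$confusion), rep$mean_accuracy)
})

test_that("a label-permuting stub sits at chance level on balanced classes", {
  idx <- generate_dataset(get_preset("demo5"), images_per_class = 4,
                          size = c(64, 64), seed = 5)
  draw <- new.env(); draw$i <- 0
  shuffler <- classifier_config("custom",
    train_fun = function(x, y, seed) sort(unique(y)),
    predict_fun = function(classes, x, truth) {
      draw$i <- draw$i + 1
      withr::with_seed(1000 + draw$i, sample(classes, nrow(x), replace = TRUE))
    })
  rep <- run_repeated_eval(idx, encoder_config(), shuffler, recipe = "FC-toy",
                           repeats = 10, per_class_train = 2, seed = 6)
  n_total <- sum(rep$confusion)
  se <- sqrt(0.2 * 0.8 / n_total)
  expect_lt(abs(rep$mean_accuracy - 0.2), 3 * se + 1e-12)
})

test_that("the encoder is fitted on training descriptors only", {
  specs <- get_preset("demo5")[1:2]
  idx_a <- generate_dataset(specs, images_per_class = 4, size = c(64, 64), seed = 7)
  plan <- make_split(idx_a, per_class_train = 2, seed = 1)
  tr <- bactex:::split_rows(plan, idx_a, "train")
  te <- bactex:::split_rows(plan, idx_a, "test")
  imgs <- lapply(seq_len(nrow(idx_a)), function(i) load_entry(idx_a, i))
  cfg <- fast_encoder_config()
  enc1 <- fit_encoder(imgs[tr], "FV-SIFT", cfg, seed = 9)
  # replace every test image by unrelated noise: fitted GMM must not move
  imgs2 <- imgs
  for (i in te) imgs2[[i]] <- noise_image(64, 64, seed = 100 + i)
  enc2 <- fit_encoder(imgs2[tr], "FV-SIFT", cfg, seed = 9)
  expect_identical(enc1$parts[["FV-SIFT"]]$gmm$means,
                   enc2$parts[["FV-SIFT"]]$gmm$means)
})

test_that("scalability bookkeeping records one accuracy per (n, repeat)", {
  idx <- generate_dataset(get_preset("demo5"), images_per_class = 4,
                          size = c(64, 64), seed = 10)
  oracle <- classifier_config("custom",
                              train_fun = function(x, y, seed) NULL,
                              predict_fun = function(state, x, truth) truth)
  res <- scalability_experiment(idx, encoder_config(), oracle, recipe = "FC-toy",
                                n_values = 3, repeats = 2, per_class_train = 2,
                                seed = 11)
  expect_equal(nrow(res$points), 2)
  expect_equal(res$points$n, c(3, 3))
  expect_equal(res$points$accuracy, c(1, 1))
  expect_error(scalability_experiment(idx, n_values = 10, seed = 1),
               "exceeds")
})

test_that("linear extrapolation recovers exact and noisy lines", {
  n_vals <- seq(3, 31, by = 3)
  pts <- expand.grid(n = n_vals, rep = 1:3)
  pts$accuracy <- (-0.2 * pts$n + 100) / 100
  res <- structure(list(points = pts, n_values = n_vals), class = "scalability_result")
  ext <- linear_extrapolation(res, target_classes = 100)
  expect_equal(ext$slope, -0.2, tolerance = 1e-10)
  expect_equal(ext$intercept, 100, tolerance = 1e-10)
  expect_equal(ext$prediction, 80, tolerance = 1e-10)
  expect_equal(ext$uncertainty, 0, tolerance = 1e-10)

  # constant accuracies: slope 0, prediction equals the constant
  pts2 <- pts; pts2$accuracy <- 0.7
  ext2 <- linear_extrapolation(structure(list(points = pts2),
                                         class = "scalability_result"), 100)
  expect_equal(ext2$slope, 0, tolerance = 1e-10)
  expect_equal(ext2$prediction, 70, tolerance = 1e-10)

  # seeded Gaussian noise around a known line: slope within 3 standard errors
  pts3 <- expand.grid(n = n_vals, rep = 1:25)
  pts3$accuracy <- (-0.3 * pts3$n + 95 +
                      withr::with_seed(12, rnorm(nrow(pts3), 0, 0.5))) / 100
  res3 <- structure(list(points = pts3), class = "scalability_result")
  ext3 <- linear_extrapolation(res3, 100)
  fit <- lm(I(100 * accuracy) ~ n, data = pts3)
  se_slope <- summary(fit)$coefficients["n", "Std. Error"]
  expect_lt(abs(ext3$slope - (-0.3)), 3 * se_slope)

  one_n <- structure(list(points = data.frame(n = 3, rep = 1, accuracy = 1)),
                     class = "scalability_result")
  expect_error(linear_extrapolation(one_n), "two distinct")
})
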