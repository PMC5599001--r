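test_that("scan_dataset indexes a class-per-directory tree deterministically", {
  root <- withr::local_tempdir()
  write_tiny_dataset(root, n_classes = 5, n_images = 20)
  idx <- scan_dataset(root)
  expect_s3_class(idx, "dataset_index")
  expect_equal(nrow(idx), 100)
  expect_equal(length(index_classes(idx)), 5)
  expect_true(all(idx$label %in% index_classes(idx)))
  # re-scan gives the identical order; matches an independent directory walk
  idx2 <- scan_dataset(root)
  expect_identical(as.data.frame(idx), as.data.frame(idx2))
  walk <- sort(list.files(root, recursive = TRUE, full.names = TRUE))
  expect_setequal(idx$source, walk)

  one <- withr::local_tempdir()
  write_tiny_dataset(one, n_classes = 1, n_images = 1)
  idx1 <- scan_dataset(one)
  expect_equal(nrow(idx1), 1)
  expect_equal(index_classes(idx1), "1.1")

  empty <- withr::local_tempdir()
  expect_error(scan_dataset(empty), "no classes")
})

test_that("class IDs sort by numeric major.minor order", {
  expect_equal(order_class_ids(c("10.10", "2.1", "10.2", "1.1")),
               c("1.1", "2.1", "10.2", "10.10"))
})

test_that("grayscale conversion applies ITU-R 601 luminance weights", {
  tmp <- withr::local_tempfile(fileext = ".png")
  arr <- withr::with_seed(3, array(runif(24 * 24 * 3), c(24, 24, 3)))
  png::writePNG(arr, tmp)
  img <- load_grayscale(tmp, label = "x")
  arr8 <- round(arr * 255) / 255  # PNG stores 8-bit
  expected <- 0.299 * arr8[, , 1] + 0.587 * arr8[, , 2] + 0.114 * arr8[, , 3]
  expect_lt(max(abs(img$pixels - expected)), 1e-6)

  gray <- matrix(128 / 255, 24, 24)
  png::writePNG(array(rep(gray, 3), c(24, 24, 3)), tmp)
  uni <- load_grayscale(tmp)
  expect_true(all(abs(uni$pixels - 128 / 255) < 1e-6))

  png::writePNG(matrix(0, 24, 24), tmp)
  expect_true(all(load_grayscale(tmp)$pixels == 0))

  # idempotent on an in-range grayscale matrix
  m <- withr::with_seed(4, matrix(runif(20 * 20), 20, 20))
  expect_identical(load_grayscale(m)$pixels, m)
  expect_error(load_grayscale("does/not/exist.png"), "exist|read")
})

test_that("splits are balanced, disjoint, seeded, and cover the index", {
  root <- withr::local_tempdir()
  write_tiny_dataset(root, n_classes = 3, n_images = 20)
  idx <- scan_dataset(root)
  for (seed in 1:100) {
    plan <- make_split(idx, per_class_train = 10, seed = seed)
    for (cl in plan$classes) {
      expect_length(plan$train[[cl]], 10)
      expect_length(plan$test[[cl]], 10)
      expect_length(intersect(plan$train[[cl]], plan$test[[cl]]), 0)
      expect_setequal(c(plan$train[[cl]], plan$test[[cl]]),
                      idx$source[idx$label == cl])
    }
  }
  expect_identical(make_split(idx, 10, seed = 7), make_split(idx, 10, seed = 7))
  expect_error(make_split(idx, per_class_train = 11), "class '1.1' has 20")
})

test_that("a 2x4 index splits 2/2 per class with exact membership", {
  idx <- dataset_index(data.frame(
    source = sprintf("s%d", 1:8),
    label = rep(c("1.1", "2.1"), each = 4)))
  plan <- make_split(idx, per_class_train = 2, seed = 3)
  for (cl in c("1.1", "2.1")) {
    expect_length(plan$train[[cl]], 2)
    expect_length(plan$test[[cl]], 2)
    expect_setequal(c(plan$train[[cl]], plan$test[[cl]]),
                    idx$source[idx$label == cl])
  }
})

test_that("split plans round-trip through JSON", {
  idx <- dataset_index(data.frame(
    source = sprintf("s%d", 1:12),
    label = rep(c("1.1", "2.1", "3.1"), each = 4)))
  plan <- make_split(idx, per_class_train = 2, seed = 9)
  path <- withr::local_tempfile(fileext = ".json")
  split_to_json(plan, path)
  back <- split_from_json(path)
  expect_equal(back$seed, plan$seed)
  expect_equal(back$train, plan$train)
  expect_equal(back$test, plan$test)
})

test_that("the size cap downscales with preserved aspect ratio", {
  img <- noise_image(80, 40, seed = 5)
  small <- load_grayscale(img, max_side = 40)
  expect_equal(dim(small$pixels), c(40, 20))
  expect_true(all(small$pixels >= 0 & small$pixels <= 1))
})
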