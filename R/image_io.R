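# Loading labeled image collections, grayscale conversion, train/test splits.
#
# Directory layout: root/<class_id>/<image>.{png,tif,tiff,jpg,jpeg,bmp} with
# one subdirectory per genus/species ID (e.g. "18.2"). Pixels are stored as
# H x W matrices of intensities in [0, 1], 0-based (row, col) coordinates.

IMAGE_EXTENSIONS <- c("png", "tif", "tiff", "jpg", "jpeg", "bmp")

# ITU-R 601 luminance weights; the descriptors downstream are gradient-based,
# so color is reduced up front.
LUMA_WEIGHTS <- c(0.299, 0.587, 0.114)

#' Construct a labeled image
#'
#' @param pixels numeric H x W matrix of intensities in \[0, 1\].
#' @param label class ID string (e.g. `"18.2"`).
#' @param source originating file path, or `"synthetic"`.
#' @return an object of class `labeled_image`.
#' @export
labeled_image <- function(pixels, label = NA_character_, source = "synthetic") {
  if (!is.matrix(pixels) || !is.numeric(pixels)) {
    stopf("pixels must be a numeric matrix")
  }
  if (nrow(pixels) < 16 || ncol(pixels) < 16) {
    stopf("image must be at least 16 x 16 (got %d x %d)", nrow(pixels), ncol(pixels))
  }
  if (any(!is.finite(pixels)) || any(pixels < 0) || any(pixels > 1)) {
    stopf("intensities must be finite and within [0, 1]")
  }
  structure(list(pixels = pixels, label = label, source = source),
            class = "labeled_image")
}

#' @export
print.labeled_image <- function(x, ...) {
  cat(sprintf("<labeled_image> %d x %d, label = %s, source = %s\n",
              nrow(x$pixels), ncol(x$pixels), x$label, x$source))
  invisible(x)
}

as_pixels <- function(image) {
  if (inherits(image, "labeled_image")) image$pixels else image
}

# bilinear resampling used for the optional size cap and backend canonical input
resize_bilinear <- function(px, new_h, new_w) {
  h <- nrow(px); w <- ncol(px)
  if (h == new_h && w == new_w) return(px)
  # map target pixel centers into source coordinates (0-based)
  ry <- (seq_len(new_h) - 0.5) * h / new_h - 0.5
  rx <- (seq_len(new_w) - 0.5) * w / new_w - 0.5
  ry <- pmin(pmax(ry, 0), h - 1)
  rx <- pmin(pmax(rx, 0), w - 1)
  y0 <- pmin(floor(ry), h - 2); x0 <- pmin(floor(rx), w - 2)
  fy <- ry - y0; fx <- rx - x0
  a <- px[cbind(rep(y0 + 1, new_w), rep(x0 + 1, each = new_h))]
  b <- px[cbind(rep(y0 + 1, new_w), rep(x0 + 2, each = new_h))]
  c_ <- px[cbind(rep(y0 + 2, new_w), rep(x0 + 1, each = new_h))]
  d <- px[cbind(rep(y0 + 2, new_w), rep(x0 + 2, each = new_h))]
  wy <- rep(fy, new_w); wx <- rep(fx, each = new_h)
  out <- (1 - wy) * (1 - wx) * a + (1 - wy) * wx * b +
    wy * (1 - wx) * c_ + wy * wx * d
  matrix(out, new_h, new_w)
}

read_image_file <- function(path) {
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    png  = tryCatch(png::readPNG(path), error = function(e) {
      stopf("failed to read PNG '%s': %s", path, conditionMessage(e))
    }),
    tif  = ,
    tiff = tryCatch(tiff::readTIFF(path), error = function(e) {
      stopf("failed to read TIFF '%s': %s", path, conditionMessage(e))
    }),
    jpg  = ,
    jpeg = {
      if (!requireNamespace("EBImage", quietly = TRUE)) {
        stopf("reading JPEG '%s' requires the EBImage package", path)
      }
      img <- EBImage::readImage(path)
      a <- EBImage::imageData(img)
      # EBImage stores x (col) as first dimension
      if (length(dim(a)) == 2) t(a) else aperm(a, c(2, 1, 3))
    },
    stopf("unsupported image format '%s' for '%s'", ext, path)
  )
  arr
}

#' Load an image as grayscale intensities in \[0, 1\]
#'
#' Multi-channel inputs are reduced with ITU-R 601 luminance weights
#' (0.299, 0.587, 0.114); an alpha channel, if present, is ignored.
#' Optionally downscales so the longest side does not exceed `max_side`
#' (aspect preserved, bilinear).
#'
#' @param source a file path, a numeric matrix of intensities in \[0, 1\],
#'   or a `labeled_image` (returned unchanged up to resizing).
#' @param label class ID to attach.
#' @param max_side optional cap on the longest image side in pixels
#'   (default `Inf`, i.e. no resizing).
#' @return a [labeled_image()].
#' @export
load_grayscale <- function(source, label = NA_character_, max_side = Inf) {
  if (inherits(source, "labeled_image")) {
    px <- source$pixels
    if (is.na(label)) label <- source$label
    src <- source$source
  } else if (is.matrix(source) && is.numeric(source)) {
    px <- source
    src <- "synthetic"
  } else if (is.character(source) && length(source) == 1) {
    arr <- read_image_file(source)
    px <- if (length(dim(arr)) == 3) {
      nch <- dim(arr)[3]
      if (nch >= 3) {
        LUMA_WEIGHTS[1] * arr[, , 1] + LUMA_WEIGHTS[2] * arr[, , 2] +
          LUMA_WEIGHTS[3] * arr[, , 3]
      } else {
        arr[, , 1]
      }
    } else {
      arr
    }
    src <- source
  } else {
    stopf("source must be a path, a numeric matrix, or a labeled_image")
  }
  px <- pmin(pmax(px, 0), 1)
  if (is.finite(max_side) && max(dim(px)) > max_side) {
    sc <- max_side / max(dim(px))
    px <- resize_bilinear(px, max(16L, as.integer(round(nrow(px) * sc))),
                          max(16L, as.integer(round(ncol(px) * sc))))
    px <- pmin(pmax(px, 0), 1)
  }
  labeled_image(px, label = label, source = src)
}

#' Build a dataset index
#'
#' @param entries data.frame with columns `source` and `label`.
#' @param images optional list of in-memory `labeled_image` objects parallel
#'   to the rows of `entries` (used by the synthetic generator).
#' @return an object of class `dataset_index`: the entries data.frame with a
#'   `classes` attribute holding unique labels in numeric major.minor order.
#' @export
dataset_index <- function(entries, images = NULL) {
  stopifnot(is.data.frame(entries), all(c("source", "label") %in% names(entries)))
  if (anyDuplicated(entries$source)) stopf("duplicate sources in index")
  rownames(entries) <- NULL
  structure(entries,
            classes = order_class_ids(unique(entries$label)),
            images = images,
            class = c("dataset_index", "data.frame"))
}

#' @export
print.dataset_index <- function(x, ...) {
  cat(sprintf("<dataset_index> %d images, %d classes: %s\n",
              nrow(x), length(attr(x, "classes")),
              paste(utils::head(attr(x, "classes"), 8), collapse = ", ")))
  invisible(x)
}

#' Class labels of a dataset index
#' @param index a [dataset_index()].
#' @return character vector of class IDs in reporting order.
#' @export
index_classes <- function(index) attr(index, "classes")

#' Load one entry of a dataset index as a labeled image
#' @param index a [dataset_index()].
#' @param i row number.
#' @param max_side optional size cap, see [load_grayscale()].
#' @return a [labeled_image()].
#' @export
load_entry <- function(index, i, max_side = Inf) {
  imgs <- attr(index, "images")
  if (!is.null(imgs)) {
    img <- imgs[[i]]
    if (is.finite(max_side)) img <- load_grayscale(img, max_side = max_side)
    return(img)
  }
  load_grayscale(index$source[i], label = index$label[i], max_side = max_side)
}

#' Restrict a dataset index to a subset of classes
#' @param index a [dataset_index()].
#' @param classes class IDs to keep.
#' @return a [dataset_index()] with only those classes.
#' @export
subset_index <- function(index, classes) {
  missing <- setdiff(classes, index_classes(index))
  if (length(missing)) stopf("unknown classes: %s", paste(missing, collapse = ", "))
  keep <- index$label %in% classes
  imgs <- attr(index, "images")
  dataset_index(as.data.frame(index)[keep, , drop = FALSE],
                images = if (!is.null(imgs)) imgs[keep])
}

#' Scan a DIBaS-style directory tree into a dataset index
#'
#' One subdirectory per class; every readable image file becomes one entry
#' labeled with the subdirectory name. Entry order is deterministic
#' (lexicographic within class).
#'
#' @param root_dir dataset root directory.
#' @return a [dataset_index()].
#' @export
scan_dataset <- function(root_dir) {
  if (!dir.exists(root_dir)) stopf("dataset root '%s' does not exist", root_dir)
  subs <- sort(basename(list.dirs(root_dir, recursive = FALSE)))
  if (!length(subs)) stopf("no classes found in '%s'", root_dir)
  parts <- list()
  for (cl in subs) {
    files <- sort(list.files(file.path(root_dir, cl)))
    ok <- tolower(tools::file_ext(files)) %in% IMAGE_EXTENSIONS
    if (any(!ok)) {
      warnf("class '%s': skipping %d file(s) with unsupported extension", cl, sum(!ok))
    }
    files <- files[ok]
    if (length(files)) {
      parts[[cl]] <- data.frame(source = file.path(root_dir, cl, files),
                                label = cl, stringsAsFactors = FALSE)
    }
  }
  if (!length(parts)) stopf("no classes found in '%s'", root_dir)
  dataset_index(do.call(rbind, c(parts, list(make.row.names = FALSE))))
}

#' Seeded per-class train/test split
#'
#' Each class is split into equally sized, disjoint train and test sets of
#' `per_class_train` images each by uniform sampling without replacement.
#' Per-class sub-seeds are `seed + class position` so adding a class leaves
#' the other classes' splits unchanged.
#'
#' @param index a [dataset_index()].
#' @param per_class_train images per class in the training set (default 10,
#'   the equal 330/330 protocol for a 33 x 20 dataset).
#' @param seed integer seed; the same seed always regenerates the same plan.
#' @return an object of class `split_plan`: per-class `train` and `test`
#'   source lists plus the seed.
#' @export
make_split <- function(index, per_class_train = 10L, seed = 1L) {
  classes <- index_classes(index)
  k <- as.integer(per_class_train)
  plan <- list(seed = as.integer(seed), per_class_train = k,
               classes = classes, train = list(), test = list())
  for (ci in seq_along(classes)) {
    rows <- which(index$label == classes[ci])
    if (length(rows) < 2L * k) {
      stopf("class '%s' has %d images; need at least %d for a %d/%d split",
            classes[ci], length(rows), 2L * k, k, k)
    }
    picked <- withr::with_seed(seed + ci, sample(rows, 2L * k))
    plan$train[[classes[ci]]] <- index$source[picked[seq_len(k)]]
    plan$test[[classes[ci]]] <- index$source[picked[k + seq_len(k)]]
  }
  structure(plan, class = "split_plan")
}

#' @export
print.split_plan <- function(x, ...) {
  cat(sprintf("<split_plan> %d classes, %d/%d per class, seed %d\n",
              length(x$classes), x$per_class_train, x$per_class_train, x$seed))
  invisible(x)
}

split_rows <- function(plan, index, which = c("train", "test")) {
  which <- match.arg(which)
  src <- unlist(plan[[which]], use.names = FALSE)
  m <- match(src, index$source)
  if (anyNA(m)) stopf("split plan references sources missing from the index")
  m
}

#' Serialize a split plan to JSON
#' @param plan a `split_plan`.
#' @param path optional output file; when `NULL` the JSON string is returned.
#' @return the JSON string, invisibly when written to a file.
#' @export
split_to_json <- function(plan, path = NULL) {
  obj <- list(seed = plan$seed, per_class_train = plan$per_class_train,
              splits = lapply(stats::setNames(plan$classes, plan$classes), function(cl) {
                list(train = plan$train[[cl]], test = plan$test[[cl]])
              }))
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  if (is.null(path)) return(as.character(js))
  writeLines(js, path)
  invisible(as.character(js))
}

#' Read a split plan back from JSON
#' @param path file written by [split_to_json()].
#' @return a `split_plan`.
#' @export
split_from_json <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  classes <- names(obj$splits)
  structure(list(seed = as.integer(obj$seed),
                 per_class_train = as.integer(obj$per_class_train),
                 classes = classes,
                 train = lapply(obj$splits, function(s) unlist(s$train)),
                 test = lapply(obj$splits, function(s) unlist(s$test))),
            class = "split_plan")
}
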