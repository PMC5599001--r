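# Pluggable backends for deep local descriptors. A backend supplies a
# convolutional extractor (image -> descriptor field, the analogue of
# truncating a network at its last convolutional layer) and an FC extractor
# (image -> fixed-length vector, the analogue of the penultimate
# fully-connected layer). Pretrained ImageNet networks (AlexNet "AN",
# VGG-M "M", VGG-VD "VD") are an optional adapter: they can be registered by
# the user, but nothing in this package requires their weights. A seeded toy
# filter-bank backend exercises the FV-CNN / FC-CNN code paths end to end.

.backend_registry <- new.env(parent = emptyenv())

#' Define a feature backend
#'
#' @param name backend tag (e.g. `"toy"`, `"AN"`, `"M"`, `"VD"`).
#' @param conv_fun function `(labeled_image) -> descriptor_field`.
#' @param fc_fun function `(labeled_image) -> numeric vector` of fixed length.
#' @param input_size canonical square input side for the FC path, or `NULL`.
#' @return an object of class `feature_backend`.
#' @export
feature_backend <- function(name, conv_fun, fc_fun, input_size = NULL) {
  stopifnot(is.character(name), is.function(conv_fun), is.function(fc_fun))
  structure(list(name = name, conv_fun = conv_fun, fc_fun = fc_fun,
                 input_size = input_size),
            class = "feature_backend")
}

#' Register a backend under its name
#' @param backend a [feature_backend()].
#' @return the backend, invisibly.
#' @export
register_backend <- function(backend) {
  stopifnot(inherits(backend, "feature_backend"))
  assign(backend$name, backend, envir = .backend_registry)
  invisible(backend)
}

#' Look up a registered backend
#'
#' Unregistered backends (e.g. `"M"` without user-supplied weights) raise a
#' "backend not available" error; there is no silent fallback.
#'
#' @param name backend tag.
#' @return a [feature_backend()].
#' @export
get_backend <- function(name) {
  if (inherits(name, "feature_backend")) return(name)
  if (!exists(name, envir = .backend_registry, inherits = FALSE)) {
    stopf("backend not available: '%s' (registered: %s)", name,
          paste(ls(.backend_registry), collapse = ", ") %||% "none")
  }
  get(name, envir = .backend_registry, inherits = FALSE)
}

#' Seeded toy filter-bank backend
#'
#' A minimal stand-in for a convolutional feature extractor: `n_filters`
#' seeded random 3 x 3 filters applied with the given stride (zero padding)
#' and half-wave rectification. The conv field on an H x W image is a
#' `ceiling(H/stride) x ceiling(W/stride)` grid of `n_filters`-dimensional
#' descriptors; the FC vector is the global average and maximum of each
#' channel (length `2 * n_filters`), computed on the image resized to the
#' backend's canonical input.
#'
#' @param seed integer seed for the filter bank.
#' @param n_filters number of filters (default 8).
#' @param stride sampling stride in pixels (default 4).
#' @param input_size canonical square input side for the FC path (default 64).
#' @return a [feature_backend()] named `"toy"`.
#' @export
toy_backend <- function(seed = 42L, n_filters = 8L, stride = 4L, input_size = 64L) {
  filters <- withr::with_seed(seed, array(stats::rnorm(9 * n_filters), c(3, 3, n_filters)))
  conv <- function(image) {
    px <- as_pixels(image)
    h <- nrow(px); w <- ncol(px)
    # replicate-edge padding keeps convolution translation-uniform
    pad <- px[c(1, 1:h, h), c(1, 1:w, w)]
    rows <- seq(1L, h, by = stride)   # 0-based centers: 0, stride, ...
    cols <- seq(1L, w, by = stride)
    nr <- length(rows); nc <- length(cols)
    desc <- matrix(0, nr * nc, n_filters)
    for (f in seq_len(n_filters)) {
      acc <- matrix(0, nr, nc)
      for (dr in 0:2) for (dc in 0:2) {
        acc <- acc + filters[dr + 1, dc + 1, f] * pad[rows + dr, cols + dc, drop = FALSE]
      }
      desc[, f] <- as.vector(t(acc))  # row-major grid order
    }
    desc <- pmax(desc, 0)  # rectification
    locations <- cbind(row = rep(rows - 1L, each = nc), col = rep(cols - 1L, nr))
    descriptor_field(locations, desc, grid_shape = c(nr, nc))
  }
  fc <- function(image) {
    px <- as_pixels(image)
    px <- resize_bilinear(px, input_size, input_size)
    fld <- conv(labeled_image(pmin(pmax(px, 0), 1)))
    c(colMeans(fld$descriptors), apply(fld$descriptors, 2, max))
  }
  feature_backend("toy", conv, fc, input_size = input_size)
}

#' Extract a convolutional descriptor field
#' @param backend a [feature_backend()] or registered backend name.
#' @param image a [labeled_image()].
#' @return a [descriptor_field()].
#' @export
extract_conv_field <- function(backend, image) {
  get_backend(backend)$conv_fun(image)
}

#' Extract a fully-connected (global) descriptor vector
#' @inheritParams extract_conv_field
#' @return numeric vector of the backend's fixed FC length.
#' @export
extract_fc_vector <- function(backend, image) {
  as.numeric(get_backend(backend)$fc_fun(image))
}

# default registry: the toy backend is always available
register_default_backends <- function() {
  register_backend(toy_backend())
}
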