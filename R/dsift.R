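# Dense SIFT: gradient-orientation histograms (4 x 4 spatial bins x 8
# orientations = 128 dims) sampled on a regular grid, default step 2 px.
#
# Geometry: a patch of side 4*bin_size centered on each grid point; spatial
# bin centers at offsets (-1.5, -0.5, 0.5, 1.5)*bin_size from the patch
# center with triangular (bilinear) spatial weighting truncated to the patch,
# and bilinear soft-binning over 8 orientation bins. Gradients by central
# differences, so adding a constant intensity changes nothing. Patches must
# fit entirely inside the image: margin = 2*bin_size, no padding.

N_ORIENT <- 8L
N_SPATIAL <- 4L
SIFT_CLAMP <- 0.2

#' Construct a descriptor field
#'
#' A grid of D-dimensional local descriptors with their patch-center
#' locations (0-based `(row, col)`).
#'
#' @param locations N x 2 matrix of (row, col) centers.
#' @param descriptors N x D numeric matrix.
#' @param grid_shape integer `(rows, cols)` of the sampling grid, or `NULL`
#'   when the field is not a single rectangular grid.
#' @return an object of class `descriptor_field`.
#' @export
descriptor_field <- function(locations, descriptors, grid_shape = NULL) {
  locations <- as.matrix(locations)
  descriptors <- as.matrix(descriptors)
  if (nrow(locations) != nrow(descriptors)) {
    stopf("locations (%d) and descriptors (%d) disagree in length",
          nrow(locations), nrow(descriptors))
  }
  if (any(!is.finite(descriptors))) stopf("descriptors must be finite")
  if (!is.null(grid_shape) && prod(grid_shape) != nrow(descriptors)) {
    stopf("grid_shape %s inconsistent with %d descriptors",
          paste(grid_shape, collapse = "x"), nrow(descriptors))
  }
  structure(list(locations = locations, descriptors = descriptors,
                 descriptor_dim = ncol(descriptors),
                 grid_shape = grid_shape),
            class = "descriptor_field")
}

#' @export
print.descriptor_field <- function(x, ...) {
  gs <- if (is.null(x$grid_shape)) "irregular" else paste(x$grid_shape, collapse = " x ")
  cat(sprintf("<descriptor_field> %d descriptors of dim %d (grid %s)\n",
              nrow(x$descriptors), x$descriptor_dim, gs))
  invisible(x)
}

dsift_margin <- function(bin_size) 2L * as.integer(bin_size)

dsift_centers <- function(extent, step, bin_size) {
  m <- dsift_margin(bin_size)
  if (extent - 1L - m < m) return(integer(0))
  seq(m, extent - 1L - m, by = step)
}

image_gradients <- function(px) {
  h <- nrow(px); w <- ncol(px)
  gx <- matrix(0, h, w); gy <- matrix(0, h, w)
  if (w >= 3) gx[, 2:(w - 1)] <- (px[, 3:w] - px[, 1:(w - 2)]) / 2
  if (h >= 3) gy[2:(h - 1), ] <- (px[3:h, ] - px[1:(h - 2), ]) / 2
  list(gx = gx, gy = gy)
}

# per-pixel gradient magnitude spread bilinearly over the 8 orientation bins
orientation_planes <- function(gx, gy) {
  mag <- sqrt(gx^2 + gy^2)
  ang <- atan2(gy, gx) %% (2 * pi)
  o <- ang / (2 * pi / N_ORIENT)
  lo <- floor(o)
  w_hi <- o - lo
  o_lo <- as.integer(lo) %% N_ORIENT
  o_hi <- (o_lo + 1L) %% N_ORIENT
  planes <- vector("list", N_ORIENT)
  for (b in 0:(N_ORIENT - 1L)) {
    planes[[b + 1L]] <- mag * ((o_lo == b) * (1 - w_hi) + (o_hi == b) * w_hi)
  }
  planes
}

# rows: (center, spatial-bin) pairs center-major; cols: pixel coordinates.
# Triangular weight around each bin center, truncated to the 4*bin_size patch.
spatial_weight_matrix <- function(centers, extent, bin_size) {
  offsets <- (seq_len(N_SPATIAL) - 2.5) * bin_size
  px <- 0:(extent - 1L)
  out <- matrix(0, length(centers) * N_SPATIAL, extent)
  r <- 1L
  for (cc in centers) {
    inside <- abs(px - cc) < 2 * bin_size
    for (off in offsets) {
      w <- pmax(0, 1 - abs(px - (cc + off)) / bin_size)
      w[!inside] <- 0
      out[r, ] <- w
      r <- r + 1L
    }
  }
  out
}

normalize_sift_rows <- function(desc, clamp = SIFT_CLAMP) {
  nrm <- sqrt(rowSums(desc^2))
  nz <- nrm > 1e-12
  if (any(nz)) {
    desc[nz, ] <- pmin(desc[nz, , drop = FALSE] / nrm[nz], clamp)
    nrm2 <- sqrt(rowSums(desc[nz, , drop = FALSE]^2))
    desc[nz, ] <- desc[nz, , drop = FALSE] / pmax(nrm2, 1e-12)
  }
  desc[!nz, ] <- 0
  desc
}

# component index for spatial bin (a, b) (1-based row, col) and orientation o
sift_component <- function(a, b, o) ((a - 1L) * N_SPATIAL + (b - 1L)) * N_ORIENT + o

#' SIFT descriptor at one patch center
#'
#' Histogram of image gradients quantized by position within the patch
#' (4 x 4 spatial bins) and by orientation (8 bins), flattened to 128
#' components, then L2-normalized with clamping at 0.2 and renormalization.
#' Flat patches return the all-zero descriptor.
#'
#' @param image a [labeled_image()] or pixel matrix.
#' @param center `(row, col)` patch center, 0-based.
#' @param bin_size spatial bin side in pixels (patch side is `4 * bin_size`).
#' @return numeric vector of length 128.
#' @export
sift_descriptor_at <- function(image, center, bin_size = 8L) {
  px <- as_pixels(image)
  h <- nrow(px); w <- ncol(px)
  m <- dsift_margin(bin_size)
  r0 <- center[1]; c0 <- center[2]
  if (r0 < m || r0 > h - 1 - m || c0 < m || c0 > w - 1 - m) {
    stopf("patch at (%s, %s) with bin_size %d does not fit inside a %d x %d image",
          r0, c0, bin_size, h, w)
  }
  rows <- (r0 - 2 * bin_size + 1):(r0 + 2 * bin_size - 1)
  cols <- (c0 - 2 * bin_size + 1):(c0 + 2 * bin_size - 1)
  sub <- px[(min(rows) - 1):(max(rows) + 1) + 1L, (min(cols) - 1):(max(cols) + 1) + 1L]
  g <- image_gradients(sub)
  inner_r <- 2:(nrow(sub) - 1); inner_c <- 2:(ncol(sub) - 1)
  planes <- orientation_planes(g$gx[inner_r, inner_c], g$gy[inner_r, inner_c])
  offsets <- (seq_len(N_SPATIAL) - 2.5) * bin_size
  d <- numeric(N_SPATIAL * N_SPATIAL * N_ORIENT)
  for (a in seq_len(N_SPATIAL)) {
    wr <- pmax(0, 1 - abs(rows - (r0 + offsets[a])) / bin_size)
    for (b in seq_len(N_SPATIAL)) {
      wc <- pmax(0, 1 - abs(cols - (c0 + offsets[b])) / bin_size)
      wmat <- outer(wr, wc)
      for (o in seq_len(N_ORIENT)) {
        d[sift_component(a, b, o)] <- sum(planes[[o]] * wmat)
      }
    }
  }
  as.numeric(normalize_sift_rows(matrix(d, 1)))
}

#' Extract dense SIFT descriptors on a regular grid
#'
#' Samples [sift_descriptor_at()] at every grid point with the given step,
#' excluding a boundary margin of `2 * bin_size` so every patch fits inside
#' the image. Descriptors are returned in row-major grid order. The dense
#' path is vectorized (separable triangular pooling of orientation planes)
#' and agrees with the per-patch computation.
#'
#' @param image a [labeled_image()] or pixel matrix.
#' @param step grid step in pixels (default 2).
#' @param bin_size spatial bin side in pixels (default 8).
#' @return a [descriptor_field()] with 128-dimensional descriptors.
#' @export
extract_dsift <- function(image, step = 2L, bin_size = 8L) {
  px <- as_pixels(image)
  h <- nrow(px); w <- ncol(px)
  centers_r <- dsift_centers(h, step, bin_size)
  centers_c <- dsift_centers(w, step, bin_size)
  if (!length(centers_r) || !length(centers_c)) {
    stopf("image too small for dense SIFT: %d x %d needs at least %d pixels per side",
          h, w, 4L * bin_size + 1L)
  }
  g <- image_gradients(px)
  planes <- orientation_planes(g$gx, g$gy)
  wr <- spatial_weight_matrix(centers_r, h, bin_size)
  wc <- spatial_weight_matrix(centers_c, w, bin_size)
  nr <- length(centers_r); nc <- length(centers_c)
  desc <- matrix(0, nr * nc, N_SPATIAL * N_SPATIAL * N_ORIENT)
  for (o in seq_len(N_ORIENT)) {
    pooled <- wr %*% planes[[o]] %*% t(wc)  # (4*nr) x (4*nc)
    for (a in seq_len(N_SPATIAL)) {
      ridx <- seq(a, by = N_SPATIAL, length.out = nr)
      for (b in seq_len(N_SPATIAL)) {
        cidx <- seq(b, by = N_SPATIAL, length.out = nc)
        block <- pooled[ridx, cidx, drop = FALSE]
        desc[, sift_component(a, b, o)] <- as.vector(t(block))  # row-major grid
      }
    }
  }
  desc <- normalize_sift_rows(desc)
  locations <- cbind(row = rep(centers_r, each = nc), col = rep(centers_c, nr))
  descriptor_field(locations, desc, grid_shape = c(nr, nc))
}

#' Multi-scale dense SIFT
#'
#' Concatenates the descriptor fields extracted at several bin sizes; the
#' default pipeline uses a single scale.
#'
#' @inheritParams extract_dsift
#' @param bin_sizes integer vector of spatial bin sizes.
#' @return a [descriptor_field()] (no single grid shape when several scales).
#' @export
extract_dsift_multiscale <- function(image, step = 2L, bin_sizes = c(8L)) {
  fields <- lapply(bin_sizes, function(b) extract_dsift(image, step = step, bin_size = b))
  if (length(fields) == 1) return(fields[[1]])
  descriptor_field(do.call(rbind, lapply(fields, `[[`, "locations")),
                   do.call(rbind, lapply(fields, `[[`, "descriptors")))
}
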