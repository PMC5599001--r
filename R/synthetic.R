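# Seeded synthetic micrograph-like textures. Classes differ in particle
# shape (disc / rod / curved rod), size, density, and spatial arrangement
# (solitary / chain / cluster), mimicking the morphotype variation of
# Gram-stained micrographs: dark particles on a bright background with
# additive Gaussian noise. Particles may overlap (real smears overlap);
# rendering combines anti-aliased particle masks by maximum.

#' Specification of one synthetic texture class
#'
#' @param class_id label (e.g. `"1.1"`).
#' @param particle `"disc"`, `"rod"`, or `"curved_rod"`.
#' @param size_mean mean particle size in pixels (disc diameter / rod length).
#' @param size_sd size jitter (Gaussian sd, pixels).
#' @param density particles per 10^4 pixels^2.
#' @param arrangement `"solitary"`, `"chain"`, or `"cluster"`.
#' @param group_size integer range `c(min, max)` of particles per chain or
#'   cluster.
#' @param orientation_spread sd (radians) of per-particle orientation jitter
#'   around a chain direction; solitary orientations are uniform.
#' @param fg,bg foreground and background intensity levels in \[0, 1\].
#' @param noise_sigma additive Gaussian noise sd.
#' @return a list of class `texture_class_spec`.
#' @export
texture_class_spec <- function(class_id, particle = c("disc", "rod", "curved_rod"),
                               size_mean = 6, size_sd = 0.8, density = 30,
                               arrangement = c("solitary", "chain", "cluster"),
                               group_size = c(4L, 8L), orientation_spread = 0.15,
                               fg = 0.25, bg = 0.85, noise_sigma = 0.05) {
  particle <- match.arg(particle)
  arrangement <- match.arg(arrangement)
  if (density <= 0) stopf("density must be positive")
  if (size_mean < 1) stopf("particle size must be at least 1 px")
  if (any(c(fg, bg) < 0) || any(c(fg, bg) > 1)) stopf("intensities must be in [0, 1]")
  if (noise_sigma < 0) stopf("noise_sigma must be non-negative")
  structure(list(class_id = class_id, particle = particle, size_mean = size_mean,
                 size_sd = size_sd, density = density, arrangement = arrangement,
                 group_size = as.integer(group_size),
                 orientation_spread = orientation_spread,
                 fg = fg, bg = bg, noise_sigma = noise_sigma),
            class = "texture_class_spec")
}

# render one particle into the foreground mask (0-based center coordinates);
# alpha-composited by max, ~0.5 px anti-aliased edge
render_particle <- function(mask, type, center, size, theta) {
  h <- nrow(mask); w <- ncol(mask)
  half <- switch(type, disc = size / 2, rod = size / 2, curved_rod = size / 2)
  pad <- ceiling(half + 2)
  r0 <- max(0, floor(center[1] - pad)); r1 <- min(h - 1, ceiling(center[1] + pad))
  c0 <- max(0, floor(center[2] - pad)); c1 <- min(w - 1, ceiling(center[2] + pad))
  if (r0 > r1 || c0 > c1) return(mask)
  rr <- r0:r1; cc <- c0:c1
  dy <- outer(rr - center[1], rep(1, length(cc)))
  dx <- outer(rep(1, length(rr)), cc - center[2])
  d <- switch(type,
    disc = {
      sqrt(dy^2 + dx^2) - size / 2
    },
    rod = {
      width <- max(1.5, size / 3.5)
      hl <- max(0, (size - width) / 2)       # half-length of the spine segment
      u <- dx * cos(theta) + dy * sin(theta) # along the rod
      v <- -dx * sin(theta) + dy * cos(theta)
      du <- pmax(abs(u) - hl, 0)
      sqrt(du^2 + v^2) - width / 2
    },
    curved_rod = {
      width <- max(1.5, size / 3.5)
      rad <- size * 0.7                      # bending radius
      span <- size / rad                     # arc length ~ size
      ts <- seq(-span / 2, span / 2, length.out = 15)
      # arc center offset so the arc passes near the particle center
      ay <- center[1] - rad * sin(theta); ax <- center[2] - rad * cos(theta)
      dmin <- matrix(Inf, length(rr), length(cc))
      for (t in ts) {
        py <- ay + rad * sin(theta + t); px <- ax + rad * cos(theta + t)
        dmin <- pmin(dmin, sqrt(outer((rr - py)^2, rep(1, length(cc))) +
                                  outer(rep(1, length(rr)), (cc - px)^2)))
      }
      dmin - width / 2
    }
  )
  alpha <- pmin(pmax(0.5 - d, 0), 1)
  idx_r <- rr + 1L; idx_c <- cc + 1L
  mask[idx_r, idx_c] <- pmax(mask[idx_r, idx_c], alpha)
  mask
}

sample_particles <- function(spec, h, w) {
  n_target <- max(1L, round(spec$density * h * w / 1e4))
  if (n_target > h * w / 4) stopf("density too high for a %d x %d image", h, w)
  parts <- list()
  add <- function(center, theta, size) {
    parts[[length(parts) + 1]] <<- list(center = center, theta = theta, size = size)
  }
  draw_size <- function() max(1.5, stats::rnorm(1, spec$size_mean, spec$size_sd))
  n_placed <- 0L
  while (n_placed < n_target) {
    if (spec$arrangement == "solitary") {
      add(c(stats::runif(1, 0, h - 1), stats::runif(1, 0, w - 1)),
          stats::runif(1, 0, pi), draw_size())
      n_placed <- n_placed + 1L
    } else if (spec$arrangement == "chain") {
      m <- sample(spec$group_size[1]:spec$group_size[2], 1)
      p <- c(stats::runif(1, 0, h - 1), stats::runif(1, 0, w - 1))
      dir <- stats::runif(1, 0, 2 * pi)
      for (j in seq_len(m)) {
        sz <- draw_size()
        add(p, dir %% pi + stats::rnorm(1, 0, spec$orientation_spread), sz)
        dir <- dir + stats::rnorm(1, 0, spec$orientation_spread * 2)
        p <- p + sz * 0.95 * c(sin(dir), cos(dir))
        n_placed <- n_placed + 1L
      }
    } else { # cluster
      m <- sample(spec$group_size[1]:spec$group_size[2], 1)
      p <- c(stats::runif(1, 0, h - 1), stats::runif(1, 0, w - 1))
      for (j in seq_len(m)) {
        off <- stats::rnorm(2, 0, spec$size_mean * 1.1)
        add(p + off, stats::runif(1, 0, pi), draw_size())
        n_placed <- n_placed + 1L
      }
    }
  }
  parts
}

#' Generate one synthetic micrograph-like image
#'
#' Particles are placed by a seeded point process (chains advance along a
#' jittered direction, clusters disperse isotropically around a seed point),
#' rendered with anti-aliased edges at the foreground intensity, and
#' corrupted with additive Gaussian noise clipped to \[0, 1\]. Pixels are
#' quantized to 8 bits so in-memory images match their PNG round trip.
#'
#' @param spec a [texture_class_spec()].
#' @param size image size `c(H, W)`, at least 64 x 64.
#' @param seed integer seed; the same spec and seed are bit-reproducible.
#' @param positions optional n x 2 matrix of fixed particle centers
#'   (0-based row, col) bypassing the point process — a hook for tests that
#'   count rendered particles.
#' @return a [labeled_image()] labeled with `spec$class_id`.
#' @export
generate_image <- function(spec, size = c(96L, 96L), seed = 1L, positions = NULL) {
  h <- size[1]; w <- size[2]
  if (h < 64 || w < 64) stopf("image size must be at least 64 x 64")
  px <- withr::with_seed(seed, {
    mask <- matrix(0, h, w)
    parts <- if (!is.null(positions)) {
      lapply(seq_len(nrow(positions)), function(i) {
        list(center = positions[i, ], theta = stats::runif(1, 0, pi),
             size = spec$size_mean)
      })
    } else {
      sample_particles(spec, h, w)
    }
    for (p in parts) {
      mask <- render_particle(mask, spec$particle, p$center, p$size, p$theta)
    }
    img <- spec$bg + (spec$fg - spec$bg) * mask
    if (spec$noise_sigma > 0) {
      img <- img + stats::rnorm(h * w, 0, spec$noise_sigma)
    }
    pmin(pmax(img, 0), 1)
  })
  px <- round(px * 255) / 255
  labeled_image(px, label = spec$class_id, source = "synthetic")
}

#' Generate a labeled synthetic dataset
#'
#' Per-class seeded sub-streams generate `images_per_class` images for every
#' spec. With `dir = NULL` the dataset is returned as an in-memory
#' [dataset_index()]; otherwise images are written as PNG files in the
#' standard `root/<class_id>/` layout and the directory is re-scanned.
#'
#' @param specs list of [texture_class_spec()] (at least 2).
#' @param images_per_class images per class (default 20).
#' @param size image size `c(H, W)`.
#' @param seed master seed.
#' @param dir optional output directory.
#' @return a [dataset_index()].
#' @export
generate_dataset <- function(specs, images_per_class = 20L, size = c(96L, 96L),
                             seed = 1L, dir = NULL) {
  if (length(specs) < 2) stopf("need at least two class specs")
  entries <- list(); images <- list()
  for (ci in seq_along(specs)) {
    spec <- specs[[ci]]
    for (i in seq_len(images_per_class)) {
      img <- generate_image(spec, size = size,
                            seed = derive_seed(seed, ci * 1000L + i))
      tag <- sprintf("synthetic:%s:%03d", spec$class_id, i)
      entries[[length(entries) + 1]] <- data.frame(source = tag,
                                                   label = spec$class_id,
                                                   stringsAsFactors = FALSE)
      images[[length(images) + 1]] <- img
    }
  }
  idx <- dataset_index(do.call(rbind, entries), images = images)
  if (is.null(dir)) return(idx)
  for (i in seq_len(nrow(idx))) {
    cl_dir <- file.path(dir, idx$label[i])
    if (!dir.exists(cl_dir)) dir.create(cl_dir, recursive = TRUE)
    fname <- sprintf("img_%03d.png", as.integer(sub(".*:", "", idx$source[i])))
    png::writePNG(images[[i]]$pixels, file.path(cl_dir, fname))
  }
  scan_dataset(dir)
}

#' Frozen synthetic texture presets
#'
#' `"demo5"`: five classes spanning the morphotype axes (solitary discs,
#' clustered discs, solitary rods, chained rods, curved rods). `"scale12"`:
#' twelve classes for the scalability study, crossing shape, arrangement,
#' size and density. Parameters are frozen; they define the study
#' conditions for the synthetic experiments.
#'
#' @param name `"demo5"` or `"scale12"`.
#' @return list of [texture_class_spec()].
#' @export
get_preset <- function(name) {
  switch(name,
    demo5 = list(
      texture_class_spec("1.1", "disc", size_mean = 5, size_sd = 0.6,
                         density = 35, arrangement = "solitary"),
      texture_class_spec("2.1", "disc", size_mean = 5, size_sd = 0.6,
                         density = 35, arrangement = "cluster",
                         group_size = c(6L, 10L)),
      texture_class_spec("3.1", "rod", size_mean = 12, size_sd = 1.2,
                         density = 18, arrangement = "solitary"),
      texture_class_spec("4.1", "rod", size_mean = 12, size_sd = 1.2,
                         density = 18, arrangement = "chain",
                         group_size = c(4L, 7L)),
      texture_class_spec("5.1", "curved_rod", size_mean = 13, size_sd = 1.2,
                         density = 15, arrangement = "solitary")
    ),
    scale12 = list(
      texture_class_spec("1.1", "disc", size_mean = 4, density = 30, arrangement = "solitary"),
      texture_class_spec("2.1", "disc", size_mean = 7, density = 20, arrangement = "solitary"),
      texture_class_spec("3.1", "disc", size_mean = 4, density = 30, arrangement = "cluster",
                         group_size = c(6L, 10L)),
      texture_class_spec("4.1", "disc", size_mean = 7, density = 18, arrangement = "cluster",
                         group_size = c(4L, 7L)),
      texture_class_spec("5.1", "rod", size_mean = 10, density = 18, arrangement = "solitary"),
      texture_class_spec("6.1", "rod", size_mean = 15, density = 12, arrangement = "solitary"),
      texture_class_spec("7.1", "rod", size_mean = 10, density = 18, arrangement = "chain",
                         group_size = c(4L, 7L)),
      texture_class_spec("8.1", "rod", size_mean = 15, density = 10, arrangement = "chain",
                         group_size = c(3L, 5L)),
      texture_class_spec("9.1", "curved_rod", size_mean = 11, density = 15, arrangement = "solitary"),
      texture_class_spec("10.1", "curved_rod", size_mean = 16, density = 10, arrangement = "solitary"),
      texture_class_spec("11.1", "curved_rod", size_mean = 11, density = 15, arrangement = "chain",
                         group_size = c(3L, 5L)),
      texture_class_spec("12.1", "disc", size_mean = 3, density = 55, arrangement = "solitary")
    ),
    stopf("unknown preset '%s' (available: %s)", name,
          paste(list_presets(), collapse = ", "))
  )
}

#' List available synthetic presets
#' @return character vector of preset names.
#' @export
list_presets <- function() c("demo5", "scale12")
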