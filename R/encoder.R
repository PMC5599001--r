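# Representation recipes and the image -> vector encoder. A recipe is a
# string of parts joined by " & ": "FV-SIFT" (Fisher Vector over dense SIFT),
# "FV-<backend>" (FV over a backend's conv field), "FC-<backend>" (the
# backend's penultimate global vector), and the shorthand "FCFV-<backend>"
# for "FC-<backend> & FV-<backend>". The FV path is one shared code path —
# only the descriptor source and dimensionality differ between FV-SIFT and
# FV over a deep field.

#' Parse a representation recipe
#' @param recipe e.g. `"FV-SIFT"`, `"FCFV-toy"`, `"FCFV-toy & FV-SIFT"`.
#' @return list of parts, each with `kind` ("FV" or "FC"), `desc`
#'   (`"SIFT"` or a backend name) and `tag`.
#' @export
parse_recipe <- function(recipe) {
  tokens <- trimws(strsplit(recipe, "&", fixed = TRUE)[[1]])
  tokens <- tokens[nzchar(tokens)]
  if (!length(tokens)) stopf("empty recipe")
  parts <- list()
  for (tok in tokens) {
    m <- regmatches(tok, regexec("^(FCFV|FV|FC)-(.+)$", tok))[[1]]
    if (!length(m)) stopf("unparseable recipe part '%s'", tok)
    kind <- m[2]; desc <- m[3]
    if (kind == "FCFV") {
      if (desc == "SIFT") stopf("FCFV requires a backend, not SIFT")
      parts <- c(parts, list(list(kind = "FC", desc = desc, tag = paste0("FC-", desc)),
                             list(kind = "FV", desc = desc, tag = paste0("FV-", desc))))
    } else {
      if (kind == "FC" && desc == "SIFT") stopf("FC-SIFT is not a valid part")
      parts <- c(parts, list(list(kind = kind, desc = desc,
                                  tag = paste0(kind, "-", desc))))
    }
  }
  # drop duplicate tags, keep first occurrence order
  tags <- vapply(parts, `[[`, "", "tag")
  parts[!duplicated(tags)]
}

#' Encoder configuration
#'
#' @param step dense SIFT grid step in pixels (default 2).
#' @param bin_size dense SIFT spatial bin size in pixels (default 8).
#' @param gmm_k number of GMM components (default 64).
#' @param pca_dim PCA dimension for SIFT descriptors before the GMM
#'   (default 64; 0 disables).
#' @param pca_dim_conv PCA dimension for deep conv descriptors (default 0,
#'   i.e. off).
#' @param fv_norm Fisher Vector normalization: `"ssr_l2"`, `"ssr"`, `"none"`.
#' @param subsample maximum pooled training descriptors used to fit PCA/GMM
#'   (default 100000).
#' @param backend backend name for deep parts (default `"toy"`).
#' @param max_side optional image size cap (longest side, pixels).
#' @return a list of class `encoder_config`.
#' @export
encoder_config <- function(step = 2L, bin_size = 8L, gmm_k = 64L, pca_dim = 64L,
                           pca_dim_conv = 0L, fv_norm = "ssr_l2",
                           subsample = 100000L, backend = "toy", max_side = Inf) {
  structure(list(step = as.integer(step), bin_size = as.integer(bin_size),
                 gmm_k = as.integer(gmm_k), pca_dim = as.integer(pca_dim),
                 pca_dim_conv = as.integer(pca_dim_conv), fv_norm = fv_norm,
                 subsample = as.integer(subsample), backend = backend,
                 max_side = max_side),
            class = "encoder_config")
}

# raw (un-pooled) features for one part of one image
extract_part_raw <- function(part, image, cfg) {
  if (part$kind == "FC") {
    extract_fc_vector(part$desc, image)
  } else if (part$desc == "SIFT") {
    extract_dsift(image, step = cfg$step, bin_size = cfg$bin_size)
  } else {
    extract_conv_field(part$desc, image)
  }
}

pool_descriptors <- function(fields, subsample, seed) {
  x <- do.call(rbind, lapply(fields, function(f) f$descriptors))
  if (nrow(x) > subsample) {
    keep <- withr::with_seed(seed, sample.int(nrow(x), subsample))
    x <- x[keep, , drop = FALSE]
  }
  x
}

#' Fit the pooling encoder on training images
#'
#' For every FV part of the recipe, pools the training descriptors
#' (subsampled to `cfg$subsample`), optionally fits a PCA, and fits the
#' diagonal-covariance GMM. FC parts need no fitting. Only the supplied
#' (training) images influence the fitted models.
#'
#' @param images list of [labeled_image()] objects (the training half).
#' @param recipe representation recipe string, see [parse_recipe()].
#' @param cfg an [encoder_config()].
#' @param seed integer seed.
#' @param raw optional precomputed raw features: `raw[[tag]][[i]]` for image
#'   i (used by the evaluation loop to avoid re-extraction).
#' @return an object of class `bactex_encoder`.
#' @export
fit_encoder <- function(images, recipe, cfg = encoder_config(), seed = 1L,
                        raw = NULL) {
  parts <- parse_recipe(recipe)
  fitted <- list()
  for (pi in seq_along(parts)) {
    part <- parts[[pi]]
    if (part$kind == "FC") {
      fitted[[part$tag]] <- part
      next
    }
    fields <- raw[[part$tag]] %||% lapply(images, function(im) extract_part_raw(part, im, cfg))
    x <- pool_descriptors(fields, cfg$subsample, derive_seed(seed, 13L + pi))
    pca_dim <- if (part$desc == "SIFT") cfg$pca_dim else cfg$pca_dim_conv
    pca <- NULL
    if (pca_dim > 0 && pca_dim < ncol(x)) {
      pca <- fit_pca(x, pca_dim)
      x <- apply_pca(pca, x)
    }
    gmm <- fit_gmm(x, K = cfg$gmm_k, seed = derive_seed(seed, 29L + pi))
    fitted[[part$tag]] <- c(part, list(pca = pca, gmm = gmm))
  }
  structure(list(recipe = recipe, parts = fitted, cfg = cfg, seed = as.integer(seed)),
            class = "bactex_encoder")
}

#' @export
print.bactex_encoder <- function(x, ...) {
  cat(sprintf("<bactex_encoder> recipe '%s' (%d part(s)), dim %d\n",
              x$recipe, length(x$parts), encoder_dim(x)))
  invisible(x)
}

#' Total encoded representation dimension
#' @param encoder a [fit_encoder()] object.
#' @return integer dimension of [encode_image()] output.
#' @export
encoder_dim <- function(encoder) {
  sum(vapply(encoder$parts, function(p) {
    if (p$kind == "FC") {
      length(extract_fc_vector(p$desc, labeled_image(matrix(0.5, 32, 32))))
    } else {
      2L * p$gmm$n_components * ncol(p$gmm$means)
    }
  }, 0L))
}

#' Encode one image into its pooled representation
#'
#' @param encoder a fitted [fit_encoder()] object.
#' @param image a [labeled_image()].
#' @param raw_parts optional precomputed raw features keyed by part tag.
#' @return a `fisher_vector` holding the (concatenated, normalized) vector.
#' @export
encode_image <- function(encoder, image = NULL, raw_parts = NULL) {
  reps <- lapply(encoder$parts, function(p) {
    rawv <- raw_parts[[p$tag]] %||% extract_part_raw(p, image, encoder$cfg)
    if (p$kind == "FC") {
      fc_pool(rawv, tag = p$tag)
    } else {
      encode_fv(p$gmm, rawv, pca = p$pca, normalization = encoder$cfg$fv_norm,
                tag = p$tag)
    }
  })
  if (length(reps) == 1) reps[[1]] else concat_representations(reps)
}
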