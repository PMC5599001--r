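# Versioned bundle persistence for fitted objects (encoders, classifiers,
# descriptor fields). Bundles round-trip bit-exactly through saveRDS.

BUNDLE_FORMAT <- "bactex-bundle"
BUNDLE_VERSION <- 1L

#' Save a fitted object as a versioned bundle
#' @param object any fitted object (encoder, classifier, descriptor field, ...).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
save_bundle <- function(object, path) {
  saveRDS(list(format = BUNDLE_FORMAT, version = BUNDLE_VERSION,
               kind = class(object)[1], payload = object),
          path, version = 3)
  invisible(path)
}

#' Load a bundle written by [save_bundle()]
#' @param path bundle file.
#' @param expect_kind optional class name the payload must have.
#' @return the stored object.
#' @export
load_bundle <- function(path, expect_kind = NULL) {
  obj <- readRDS(path)
  if (!is.list(obj) || !identical(obj$format, BUNDLE_FORMAT)) {
    stopf("'%s' is not a bactex bundle", path)
  }
  if (!identical(obj$version, BUNDLE_VERSION)) {
    stopf("bundle version mismatch in '%s': found %s, expected %d",
          path, obj$version, BUNDLE_VERSION)
  }
  if (!is.null(expect_kind) && !identical(obj$kind, expect_kind)) {
    stopf("bundle '%s' holds a %s, expected %s", path, obj$kind, expect_kind)
  }
  obj$payload
}
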