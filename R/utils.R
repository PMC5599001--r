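# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)

#' Derive a child seed from a master seed
#'
#' Deterministic fan-out of one master seed into per-stage sub-seeds, kept
#' within the 32-bit integer range so it can be passed to [set.seed()].
#'
#' @param seed master seed (integer).
#' @param offset integer stream offset; distinct offsets give distinct streams.
#' @return an integer seed.
#' @export
derive_seed <- function(seed, offset) {
  as.integer((abs(as.numeric(seed)) + 99991 * abs(as.numeric(offset))) %% 2147483629)
}

l2_normalize <- function(v) {
  n <- sqrt(sum(v * v))
  if (n > 0) v / n else v
}

# numeric major.minor ordering of class IDs ("10.2" before "10.10");
# non-numeric labels fall back to lexicographic order after numeric ones
order_class_ids <- function(ids) {
  parts <- strsplit(ids, ".", fixed = TRUE)
  major <- suppressWarnings(as.numeric(vapply(parts, function(p) p[1], "")))
  minor <- suppressWarnings(as.numeric(vapply(parts, function(p) {
    if (length(p) > 1) p[2] else "0"
  }, "")))
  minor[is.na(minor)] <- 0
  ids[order(is.na(major), major, minor, ids)]
}
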