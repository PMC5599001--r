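# Fisher Vector pooling: fit a diagonal-covariance GMM to local descriptors,
# softly assign each descriptor to components, and pool per-component first-
# and second-order statistics into a single 2*K*d vector. Optional PCA
# decorrelates descriptors before the diagonal GMM.

#' Fit a PCA projection
#'
#' Top-`retained_dim` principal directions of the mean-centered descriptors,
#' computed by SVD with a deterministic sign convention (the largest-magnitude
#' loading of each direction is positive).
#'
#' @param descriptors N x D numeric matrix (N > retained_dim).
#' @param retained_dim number of directions to keep (<= D).
#' @return object of class `pca_model` with fields `mean`, `basis`
#'   (D x retained_dim, orthonormal columns), `retained_dim`, `eigenvalues`.
#' @export
fit_pca <- function(descriptors, retained_dim) {
  x <- as.matrix(descriptors)
  n <- nrow(x); d_in <- ncol(x)
  if (retained_dim > d_in) stopf("retained_dim %d exceeds descriptor dim %d", retained_dim, d_in)
  if (n <= retained_dim) stopf("need more observations (%d) than retained dims (%d)", n, retained_dim)
  mu <- colMeans(x)
  xc <- sweep(x, 2, mu)
  sv <- svd(xc, nu = 0, nv = retained_dim)
  basis <- sv$v[, seq_len(retained_dim), drop = FALSE]
  for (j in seq_len(retained_dim)) {
    i <- which.max(abs(basis[, j]))
    if (basis[i, j] < 0) basis[, j] <- -basis[, j]
  }
  structure(list(mean = mu, basis = basis, retained_dim = retained_dim,
                 eigenvalues = (sv$d^2 / (n - 1))[seq_len(retained_dim)]),
            class = "pca_model")
}

#' Project descriptors through a fitted PCA
#' @param pca a [fit_pca()] model.
#' @param descriptors N x D matrix.
#' @return N x retained_dim matrix.
#' @export
apply_pca <- function(pca, descriptors) {
  x <- as.matrix(descriptors)
  if (ncol(x) != length(pca$mean)) {
    stopf("descriptor dim %d does not match PCA input dim %d", ncol(x), length(pca$mean))
  }
  sweep(x, 2, pca$mean) %*% pca$basis
}

# per-component diagonal-Gaussian log densities, N x K
gmm_log_densities <- function(gmm, x) {
  k <- gmm$n_components
  d <- ncol(gmm$means)
  out <- matrix(0, nrow(x), k)
  x2 <- x^2
  for (j in seq_len(k)) {
    v <- gmm$variances[j, ]
    mu <- gmm$means[j, ]
    quad <- x2 %*% (1 / v) - 2 * (x %*% (mu / v)) + sum(mu^2 / v)
    out[, j] <- -0.5 * (d * log(2 * pi) + sum(log(v)) + quad)
  }
  out
}

logsumexp_rows <- function(a) {
  m <- apply(a, 1, max)
  m + log(rowSums(exp(a - m)))
}

#' Fit a diagonal-covariance Gaussian mixture by EM
#'
#' Seeded k-means initialization followed by EM with a per-dimension variance
#' floor. The training log-likelihood is non-decreasing across iterations;
#' iteration stops when the relative improvement falls below `tol` or after
#' `max_iter` iterations. A component whose weight collapses below 1e-8 is
#' re-seeded at a random data point once; a second collapse is an error.
#'
#' @param descriptors N x d matrix with N >= 10 * K.
#' @param K number of mixture components.
#' @param seed integer seed (k-means init and any re-seeding).
#' @param max_iter maximum EM iterations (default 200).
#' @param tol relative log-likelihood improvement threshold (default 1e-6).
#' @param var_floor_frac variance floor as a fraction of the per-dimension
#'   data variance (default 1e-4).
#' @return object of class `gmm_model` with `n_components`, `weights`,
#'   `means` (K x d), `variances` (K x d), `loglik` (per-iteration trace),
#'   `converged`, `seed`.
#' @export
fit_gmm <- function(descriptors, K, seed = 1L, max_iter = 200L, tol = 1e-6,
                    var_floor_frac = 1e-4) {
  x <- as.matrix(descriptors)
  n <- nrow(x); d <- ncol(x)
  K <- as.integer(K)
  if (n < 10L * K) stopf("need at least %d descriptors for K = %d (got %d)", 10L * K, K, n)
  data_var <- apply(x, 2, stats::var)
  floor_v <- pmax(var_floor_frac * data_var, 1e-12)

  if (K == 1L) {
    means <- matrix(colMeans(x), 1)
    vars <- matrix(pmax(colMeans(sweep(x, 2, means[1, ])^2), floor_v), 1)
    ll <- sum(gmm_log_densities(list(n_components = 1L, means = means, variances = vars), x))
    return(structure(list(n_components = 1L, weights = 1, means = means,
                          variances = vars, loglik = ll, converged = TRUE,
                          n_iter = 1L, seed = as.integer(seed)),
                     class = "gmm_model"))
  }

  km <- withr::with_seed(seed, stats::kmeans(x, centers = K, nstart = 3L, iter.max = 50L))
  means <- unname(km$centers)
  weights <- pmax(km$size, 1) / sum(pmax(km$size, 1))
  vars <- matrix(0, K, d)
  for (j in seq_len(K)) {
    idx <- which(km$cluster == j)
    vars[j, ] <- if (length(idx) > 1) {
      pmax(colMeans(sweep(x[idx, , drop = FALSE], 2, means[j, ])^2), floor_v)
    } else data_var
  }
  vars <- pmax(vars, floor_v[col(vars)])

  gmm <- list(n_components = K, weights = weights, means = means, variances = vars)
  ll_trace <- numeric(0)
  reseeded <- rep(FALSE, K)
  converged <- FALSE
  it <- 0L
  repeat {
    it <- it + 1L
    a <- sweep(gmm_log_densities(gmm, x), 2, log(gmm$weights), `+`)
    lse <- logsumexp_rows(a)
    ll <- sum(lse)
    ll_trace <- c(ll_trace, ll)
    resp <- exp(a - lse)
    nk <- colSums(resp)

    dead <- which(nk / n < 1e-8)
    if (length(dead)) {
      if (any(reseeded[dead])) stopf("GMM component collapsed twice; reduce K")
      reseeded[dead] <- TRUE
      pick <- withr::with_seed(derive_seed(seed, it), sample.int(n, length(dead)))
      for (m in seq_along(dead)) {
        gmm$means[dead[m], ] <- x[pick[m], ]
        gmm$variances[dead[m], ] <- pmax(data_var, floor_v)
        gmm$weights[dead[m]] <- 1 / K
      }
      gmm$weights <- gmm$weights / sum(gmm$weights)
      ll_trace <- ll_trace[-length(ll_trace)]  # restart monotone trace after surgery
      next
    }

    gmm$weights <- nk / n
    gmm$means <- sweep(crossprod(resp, x), 1, nk, `/`)
    ex2 <- sweep(crossprod(resp, x^2), 1, nk, `/`)
    gmm$variances <- pmax(ex2 - gmm$means^2, floor_v[col(gmm$means)])

    prev <- if (length(ll_trace) > 1) ll_trace[length(ll_trace) - 1] else -Inf
    if (is.finite(prev) && (ll - prev) < tol * abs(prev)) { converged <- TRUE; break }
    if (it >= max_iter) break
  }
  structure(c(gmm, list(loglik = ll_trace, converged = converged,
                        n_iter = it, seed = as.integer(seed))),
            class = "gmm_model")
}

#' @export
print.gmm_model <- function(x, ...) {
  cat(sprintf("<gmm_model> K = %d, dim = %d, %s after %d EM iterations\n",
              x$n_components, ncol(x$means),
              if (isTRUE(x$converged)) "converged" else "not converged", x$n_iter))
  invisible(x)
}

#' Soft assignment of descriptors to GMM components
#'
#' Posterior probability of each component given a descriptor,
#' `gamma_k` proportional to `weight_k * N(x; mu_k, sigma_k^2)`, computed in
#' the log domain (log-sum-exp) so underflow cannot occur. Rows sum to one.
#'
#' @param gmm a [fit_gmm()] model.
#' @param descriptor a d-vector or an N x d matrix.
#' @return a K-vector (single descriptor) or N x K matrix of posteriors.
#' @export
soft_assign <- function(gmm, descriptor) {
  single <- is.null(dim(descriptor))
  x <- if (single) matrix(descriptor, 1) else as.matrix(descriptor)
  if (ncol(x) != ncol(gmm$means)) {
    stopf("descriptor dim %d does not match GMM dim %d", ncol(x), ncol(gmm$means))
  }
  a <- sweep(gmm_log_densities(gmm, x), 2, log(gmm$weights), `+`)
  g <- exp(a - logsumexp_rows(a))
  if (single) as.numeric(g) else g
}

#' Sample descriptors from a fitted GMM
#' @param gmm a [fit_gmm()] model.
#' @param n number of samples.
#' @param seed integer seed.
#' @return n x d matrix.
#' @export
sample_gmm <- function(gmm, n, seed = 1L) {
  d <- ncol(gmm$means)
  withr::with_seed(seed, {
    comp <- sample.int(gmm$n_components, n, replace = TRUE, prob = gmm$weights)
    z <- matrix(stats::rnorm(n * d), n, d)
    gmm$means[comp, , drop = FALSE] + z * sqrt(gmm$variances[comp, , drop = FALSE])
  })
}

apply_fv_normalization <- function(v, normalization = c("ssr_l2", "ssr", "none")) {
  normalization <- match.arg(normalization)
  if (normalization %in% c("ssr", "ssr_l2")) v <- sign(v) * sqrt(abs(v))
  if (normalization == "ssr_l2") v <- l2_normalize(v)
  v
}

new_fisher_vector <- function(values, normalization, tag) {
  structure(list(values = as.numeric(values), normalization = normalization,
                 tag = tag), class = "fisher_vector")
}

#' @export
print.fisher_vector <- function(x, ...) {
  cat(sprintf("<fisher_vector> %s, length %d, normalization %s\n",
              x$tag, length(x$values), x$normalization))
  invisible(x)
}

#' @export
as.double.fisher_vector <- function(x, ...) x$values

#' Encode a descriptor field as a Fisher Vector
#'
#' For each component k the first-order block is
#' `(1 / (N * sqrt(w_k))) * sum_i gamma_ik * (x_i - mu_k) / sigma_k` and the
#' second-order block is
#' `(1 / (N * sqrt(2 * w_k))) * sum_i gamma_ik * ((x_i - mu_k)^2 / sigma_k^2 - 1)`.
#' All first-order blocks (components ascending, dimensions within) are
#' concatenated ahead of all second-order blocks, giving length `2 * K * d`,
#' then normalized (default: signed square root followed by global L2).
#'
#' @param gmm a [fit_gmm()] model.
#' @param field a [descriptor_field()] or N x D matrix.
#' @param pca optional [fit_pca()] model applied before encoding.
#' @param normalization `"ssr_l2"` (default), `"ssr"`, or `"none"`.
#' @param posterior_floor posteriors below this value are treated as zero for
#'   speed (default 1e-8; set 0 to disable).
#' @param tag representation name stored with the vector.
#' @return a `fisher_vector` of length `2 * K * d`.
#' @export
encode_fv <- function(gmm, field, pca = NULL,
                      normalization = c("ssr_l2", "ssr", "none"),
                      posterior_floor = 1e-8, tag = "FV") {
  normalization <- match.arg(normalization)
  x <- if (inherits(field, "descriptor_field")) field$descriptors else as.matrix(field)
  if (!nrow(x)) stopf("empty descriptor field")
  if (!is.null(pca)) x <- apply_pca(pca, x)
  d <- ncol(gmm$means)
  if (ncol(x) != d) stopf("descriptor dim %d does not match GMM dim %d", ncol(x), d)
  n <- nrow(x)
  g <- soft_assign(gmm, x)
  if (is.null(dim(g))) g <- matrix(g, 1)
  if (posterior_floor > 0) g[g < posterior_floor] <- 0

  s0 <- colSums(g)                 # K
  s1 <- crossprod(g, x)            # K x d
  s2 <- crossprod(g, x^2)          # K x d
  mu <- gmm$means; v <- gmm$variances; sg <- sqrt(v)
  first <- (s1 - s0 * mu) / sg / (n * sqrt(gmm$weights))
  second <- ((s2 - 2 * mu * s1 + s0 * mu^2) / v - s0) / (n * sqrt(2 * gmm$weights))
  vals <- c(as.vector(t(first)), as.vector(t(second)))
  new_fisher_vector(apply_fv_normalization(vals, normalization), normalization, tag)
}

#' Pass a fully-connected descriptor through as a pooled representation
#'
#' The FC path has no pooling stage; the vector is only normalized (L2 by
#' default) so it can be concatenated with Fisher Vectors.
#'
#' @param vector numeric vector (e.g. a backend's penultimate-layer output).
#' @param tag representation name (e.g. `"FC-toy"`).
#' @param normalization `"l2"` (default) or `"none"`.
#' @return a `fisher_vector`-shaped representation.
#' @export
fc_pool <- function(vector, tag = "FC", normalization = c("l2", "none")) {
  normalization <- match.arg(normalization)
  v <- as.numeric(vector)
  if (any(!is.finite(v))) stopf("non-finite FC descriptor")
  if (normalization == "l2") v <- l2_normalize(v)
  new_fisher_vector(v, normalization, tag)
}

#' Concatenate pooled representations
#'
#' Each part is L2-normalized independently, the parts are concatenated, and
#' the combined vector is globally L2-normalized — the convention used for
#' combined representations such as "FCFV-M & FV-SIFT".
#'
#' @param parts list of `fisher_vector` objects or numeric vectors.
#' @param tag name for the combined representation; by default the part tags
#'   joined with `" & "`.
#' @return a `fisher_vector` holding the combined vector.
#' @export
concat_representations <- function(parts, tag = NULL) {
  if (!length(parts)) stopf("need at least one representation part")
  tags <- vapply(seq_along(parts), function(i) {
    p <- parts[[i]]
    if (inherits(p, "fisher_vector")) p$tag else sprintf("part%d", i)
  }, "")
  vecs <- lapply(parts, function(p) l2_normalize(as.numeric(if (inherits(p, "fisher_vector")) p$values else p)))
  if (any(!vapply(vecs, function(v) all(is.finite(v)), TRUE))) stopf("non-finite part")
  v <- l2_normalize(unlist(vecs, use.names = FALSE))
  new_fisher_vector(v, "l2", tag %||% paste(tags, collapse = " & "))
}
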