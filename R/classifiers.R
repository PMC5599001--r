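# Classifier family: "Original" one-vs-all linear SVM with C = 1, one-vs-one
# SVMs (linear / polynomial / RBF) with Bayes-optimized hyperparameters, and
# a boosted-tree ensemble ("rf-adaboost", multiclass AdaBoost / SAMME over
# depth-limited rpart trees). Features are standardized with training-set
# mean and variance before SVM fitting; the scaler is stored with the model.
# Decision ties break toward the lowest class index in major.minor order.

fit_standardizer <- function(x) {
  mu <- colMeans(x)
  sd <- apply(x, 2, stats::sd)
  sd[!is.finite(sd) | sd < 1e-12] <- 1
  list(mean = mu, sd = sd)
}

apply_standardizer <- function(sc, x) {
  sweep(sweep(x, 2, sc$mean), 2, sc$sd, `/`)
}

new_classifier <- function(kind, state, classes, config) {
  structure(list(kind = kind, state = state, classes = classes, config = config),
            class = "bactex_classifier")
}

#' @export
print.bactex_classifier <- function(x, ...) {
  cat(sprintf("<bactex_classifier> %s, %d classes\n", x$kind, length(x$classes)))
  invisible(x)
}

check_training_input <- function(features, labels) {
  x <- as.matrix(features)
  labels <- as.character(labels)
  if (nrow(x) != length(labels)) stopf("features and labels disagree in length")
  if (any(!is.finite(x))) stopf("features must be finite")
  classes <- order_class_ids(unique(labels))
  if (length(classes) < 2) stopf("need at least two classes")
  list(x = x, labels = labels, classes = classes)
}

#' Train the "Original" one-vs-all linear SVM (C = 1)
#'
#' One binary linear SVM per class; prediction is the argmax of the binary
#' decision values, ties broken toward the lowest class index.
#'
#' @param features N x F numeric matrix.
#' @param labels N class labels.
#' @param C soft-margin cost (default 1).
#' @return a `bactex_classifier` of kind `"ova_linear"`.
#' @export
train_original <- function(features, labels, C = 1) {
  inp <- check_training_input(features, labels)
  scaler <- fit_standardizer(inp$x)
  xs <- apply_standardizer(scaler, inp$x)
  models <- vector("list", length(inp$classes))
  flips <- logical(length(inp$classes))
  for (ci in seq_along(inp$classes)) {
    yk <- factor(ifelse(inp$labels == inp$classes[ci], "pos", "neg"),
                 levels = c("pos", "neg"))
    m <- e1071::svm(xs, yk, kernel = "linear", cost = C, scale = FALSE)
    dv <- attr(stats::predict(m, xs, decision.values = TRUE), "decision.values")[, 1]
    # orient decision values so positive means "this class"
    flips[ci] <- mean(dv[yk == "pos"]) < mean(dv[yk == "neg"])
    models[[ci]] <- m
  }
  new_classifier("ova_linear", list(models = models, flips = flips, scaler = scaler),
                 inp$classes, list(C = C))
}

cv_folds_stratified <- function(labels, k = 5L, seed = 1L) {
  fold <- integer(length(labels))
  withr::with_seed(seed, {
    for (cl in unique(labels)) {
      idx <- sample(which(labels == cl))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  fold
}

svm_from_params <- function(xs, y, kernel, params, F_dim) {
  switch(kernel,
    linear = e1071::svm(xs, y, kernel = "linear", cost = params$C, scale = FALSE),
    polynomial = e1071::svm(xs, y, kernel = "polynomial", cost = params$C,
                            degree = params$degree, gamma = 1 / F_dim, coef0 = 1,
                            scale = FALSE),
    rbf = e1071::svm(xs, y, kernel = "radial", cost = params$C,
                     gamma = params$gamma, scale = FALSE),
    stopf("unknown kernel '%s'", kernel)
  )
}

decode_svm_params <- function(kernel, x) {
  p <- list(C = 10^x[1])
  if (kernel == "rbf") p$gamma <- 10^x[2]
  if (kernel == "polynomial") p$degree <- as.integer(pmin(pmax(round(x[2]), 2), 4))
  p
}

#' SVM specification
#' @param kernel `"linear"`, `"polynomial"`, or `"rbf"`.
#' @param scheme multiclass scheme (one-vs-one for the optimized family).
#' @param C soft-margin cost.
#' @param degree polynomial degree (2-4).
#' @param gamma RBF kernel width.
#' @return a list of class `svm_spec`.
#' @export
svm_spec <- function(kernel = c("linear", "polynomial", "rbf"),
                     scheme = c("one_vs_one", "one_vs_all"),
                     C = 1, degree = 3L, gamma = NULL) {
  kernel <- match.arg(kernel)
  scheme <- match.arg(scheme)
  if (C <= 0) stopf("C must be positive")
  if (kernel == "polynomial" && !degree %in% 2:4) stopf("degree must be in {2,3,4}")
  if (!is.null(gamma) && gamma <= 0) stopf("gamma must be positive")
  structure(list(kernel = kernel, scheme = scheme, C = C, degree = degree,
                 gamma = gamma), class = "svm_spec")
}

#' Train a one-vs-one SVM with Bayes-optimized hyperparameters
#'
#' Maximizes mean 5-fold stratified cross-validated accuracy on the training
#' set over `log10(C) in [-3, 3]` (plus `log10(gamma) in [-4, 1]` for the RBF
#' kernel, and degree in 2-4 for the polynomial kernel) using
#' [bayes_optimize()], then refits on all training data with the best
#' parameters. The default configuration (C = 1) is always part of the
#' evaluated trace, so the optimum can never fall below it in CV.
#'
#' @param features N x F numeric matrix.
#' @param labels N class labels.
#' @param spec an [svm_spec()].
#' @param budget number of objective evaluations (>= 5, default 25).
#' @param seed integer seed (folds and optimizer).
#' @param cv_folds number of stratified CV folds (default 5).
#' @return a `bactex_classifier` of kind `"ovo_svm"` with the optimizer trace
#'   in its config.
#' @export
train_optimized <- function(features, labels, spec = svm_spec("linear"),
                            budget = 25L, seed = 1L, cv_folds = 5L) {
  inp <- check_training_input(features, labels)
  scaler <- fit_standardizer(inp$x)
  xs <- apply_standardizer(scaler, inp$x)
  y <- factor(inp$labels, levels = inp$classes)
  F_dim <- ncol(xs)
  folds <- cv_folds_stratified(inp$labels, k = cv_folds, seed = derive_seed(seed, 7L))

  cv_accuracy <- function(params) {
    acc <- vapply(seq_len(cv_folds), function(f) {
      tr <- folds != f
      if (length(unique(inp$labels[tr])) < 2 || !any(!tr)) return(NA_real_)
      m <- svm_from_params(xs[tr, , drop = FALSE], y[tr], spec$kernel, params, F_dim)
      mean(as.character(stats::predict(m, xs[!tr, , drop = FALSE])) == inp$labels[!tr])
    }, 0)
    mean(acc, na.rm = TRUE)
  }

  bounds <- switch(spec$kernel,
    linear = list(lower = -3, upper = 3, init = matrix(0, 1, 1)),
    rbf = list(lower = c(-3, -4), upper = c(3, 1),
               init = matrix(c(0, log10(1 / F_dim)), 1)),
    polynomial = list(lower = c(-3, 2), upper = c(3, 4), init = matrix(c(0, 3), 1))
  )
  # clamp the default point into the box
  bounds$init <- pmin(pmax(bounds$init, rep(bounds$lower, each = 1)),
                      rep(bounds$upper, each = 1))
  opt <- bayes_optimize(function(x) cv_accuracy(decode_svm_params(spec$kernel, x)),
                        bounds$lower, bounds$upper, budget = budget,
                        seed = derive_seed(seed, 11L), init = bounds$init)
  best <- decode_svm_params(spec$kernel, opt$best_x)
  model <- svm_from_params(xs, y, spec$kernel, best, F_dim)
  new_classifier("ovo_svm",
                 list(model = model, scaler = scaler),
                 inp$classes,
                 list(spec = spec, best_params = best, cv_accuracy = opt$best_y,
                      trace = opt$trace, seed = seed, budget = budget))
}

#' Train a boosted decision-tree ensemble (multiclass AdaBoost / SAMME)
#'
#' Depth-limited rpart trees boosted with the SAMME reweighting scheme. When
#' `optimize = TRUE` the estimator count and tree depth are tuned by the same
#' Bayes-optimization protocol as [train_optimized()] (5-fold stratified CV).
#'
#' @param features N x F numeric matrix.
#' @param labels N class labels.
#' @param n_estimators number of boosting rounds (default 100).
#' @param max_depth maximum tree depth (default 2).
#' @param seed integer seed.
#' @param optimize tune `n_estimators` and `max_depth` by Bayes optimization.
#' @param budget optimizer budget when `optimize = TRUE`.
#' @return a `bactex_classifier` of kind `"adaboost"`.
#' @export
train_boosted_trees <- function(features, labels, n_estimators = 100L,
                                max_depth = 2L, seed = 1L, optimize = FALSE,
                                budget = 10L) {
  inp <- check_training_input(features, labels)
  if (optimize) {
    folds <- cv_folds_stratified(inp$labels, k = 5L, seed = derive_seed(seed, 7L))
    cv_accuracy <- function(n_est, depth) {
      acc <- vapply(1:5, function(f) {
        tr <- folds != f
        m <- fit_samme(inp$x[tr, , drop = FALSE], inp$labels[tr], inp$classes,
                       n_est, depth)
        mean(samme_predict(m, inp$x[!tr, , drop = FALSE]) == inp$labels[!tr])
      }, 0)
      mean(acc)
    }
    opt <- bayes_optimize(function(x) {
      cv_accuracy(as.integer(round(x[1])), as.integer(round(x[2])))
    }, lower = c(20, 1), upper = c(200, 4), budget = budget,
    seed = derive_seed(seed, 11L), init = matrix(c(100, 2), 1))
    n_estimators <- as.integer(round(opt$best_x[1]))
    max_depth <- as.integer(round(opt$best_x[2]))
  }
  state <- fit_samme(inp$x, inp$labels, inp$classes, n_estimators, max_depth)
  new_classifier("adaboost", state, inp$classes,
                 list(n_estimators = n_estimators, max_depth = max_depth,
                      seed = seed, optimized = optimize))
}

fit_samme <- function(x, labels, classes, n_estimators, max_depth) {
  n <- nrow(x); k <- length(classes)
  df <- as.data.frame(x)
  names(df) <- paste0("f", seq_len(ncol(x)))
  df$.y <- factor(labels, levels = classes)
  w <- rep(1 / n, n)
  trees <- list(); alphas <- numeric(0)
  ctrl <- rpart::rpart.control(maxdepth = max_depth, cp = 0, minsplit = 4,
                               xval = 0, maxcompete = 0, maxsurrogate = 0)
  for (m in seq_len(n_estimators)) {
    fit <- rpart::rpart(.y ~ ., data = df, weights = w, method = "class",
                        control = ctrl)
    pred <- as.character(stats::predict(fit, df, type = "class"))
    miss <- pred != labels
    err <- sum(w * miss)
    if (err <= 1e-10) {           # perfect learner: keep it with a capped vote
      trees[[length(trees) + 1]] <- fit
      alphas <- c(alphas, log((1 - 1e-10) / 1e-10) + log(k - 1))
      break
    }
    if (err >= 1 - 1 / k) break   # no better than chance under SAMME
    alpha <- log((1 - err) / err) + log(k - 1)
    trees[[length(trees) + 1]] <- fit
    alphas <- c(alphas, alpha)
    w <- w * exp(alpha * miss)
    w <- w / sum(w)
  }
  if (!length(trees)) stopf("boosting failed: no tree beat chance level")
  list(trees = trees, alphas = alphas, feature_names = names(df)[seq_len(ncol(x))],
       classes = classes)
}

samme_predict <- function(state, x) {
  df <- as.data.frame(x)
  names(df) <- state$feature_names
  votes <- matrix(0, nrow(x), length(state$classes),
                  dimnames = list(NULL, state$classes))
  for (i in seq_along(state$trees)) {
    pred <- as.character(stats::predict(state$trees[[i]], df, type = "class"))
    votes[cbind(seq_len(nrow(x)), match(pred, state$classes))] <-
      votes[cbind(seq_len(nrow(x)), match(pred, state$classes))] + state$alphas[i]
  }
  state$classes[max.col(votes, ties.method = "first")]
}

#' Predict class labels
#'
#' @param object a `bactex_classifier`.
#' @param newdata M x F matrix with the training dimensionality.
#' @param ... unused.
#' @return character vector of M labels from the model's class list.
#' @export
predict.bactex_classifier <- function(object, newdata, ...) {
  x <- as.matrix(newdata)
  f_expected <- switch(object$kind,
    ova_linear = length(object$state$scaler$mean),
    ovo_svm = length(object$state$scaler$mean),
    adaboost = length(object$state$feature_names),
    custom = NA_integer_
  )
  if (!is.na(f_expected) && ncol(x) != f_expected) {
    stopf("feature dimension %d does not match training dimension %d",
          ncol(x), f_expected)
  }
  switch(object$kind,
    ova_linear = {
      xs <- apply_standardizer(object$state$scaler, x)
      dv <- vapply(seq_along(object$classes), function(ci) {
        m <- object$state$models[[ci]]
        v <- attr(stats::predict(m, xs, decision.values = TRUE), "decision.values")[, 1]
        if (object$state$flips[ci]) -v else v
      }, numeric(nrow(xs)))
      dv <- matrix(dv, nrow = nrow(xs))
      object$classes[max.col(dv, ties.method = "first")]
    },
    ovo_svm = {
      xs <- apply_standardizer(object$state$scaler, x)
      as.character(stats::predict(object$state$model, xs))
    },
    adaboost = samme_predict(object$state, x),
    custom = object$state$predict_fun(object$state$model, x),
    stopf("unknown classifier kind '%s'", object$kind)
  )
}
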