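# Evaluation protocols: repeated equal-split classification (accuracy,
# per-class accuracy, accumulated confusion matrix) and the class-count
# scalability study with linear extrapolation to a larger class count.
#
# Confusion convention: position (i, j) counts observations of true class i
# predicted as class j. Accuracy is the micro-average (fraction of test
# images classified correctly); per-class accuracy is reported separately.

#' Confusion matrix
#' @param true_labels,predicted_labels equal-length label vectors.
#' @param classes class list fixing row/column order.
#' @return C x C count matrix; rows are true classes, columns predictions.
#' @export
confusion_matrix <- function(true_labels, predicted_labels, classes) {
  true_labels <- as.character(true_labels)
  predicted_labels <- as.character(predicted_labels)
  if (length(true_labels) != length(predicted_labels)) {
    stopf("label vectors disagree in length")
  }
  unknown <- setdiff(unique(c(true_labels, predicted_labels)), classes)
  if (length(unknown)) stopf("unknown label(s): %s", paste(unknown, collapse = ", "))
  cm <- matrix(0L, length(classes), length(classes),
               dimnames = list(true = classes, predicted = classes))
  for (i in seq_along(true_labels)) {
    cm[true_labels[i], predicted_labels[i]] <- cm[true_labels[i], predicted_labels[i]] + 1L
  }
  cm
}

#' Per-class accuracy from a confusion matrix
#' @param confusion C x C count matrix (rows = true class).
#' @return named vector of per-class fractions (diagonal / row sum).
#' @export
per_class_accuracy <- function(confusion) {
  rs <- rowSums(confusion)
  if (any(rs == 0)) {
    stopf("class(es) with no observations: %s",
          paste(rownames(confusion)[rs == 0], collapse = ", "))
  }
  diag(confusion) / rs
}

accuracy_from_confusion <- function(confusion) {
  sum(diag(confusion)) / sum(confusion)
}

#' Classifier configuration for the evaluation protocols
#'
#' @param name `"original"` (one-vs-all linear SVM, C = 1), `"linear"`,
#'   `"poly"`, `"rbf"` (one-vs-one SVMs with Bayes-optimized parameters),
#'   `"rf-adaboost"` (boosted trees), or `"custom"`.
#' @param budget Bayes-optimization budget for the optimized variants.
#' @param C cost for `"original"`.
#' @param train_fun,predict_fun for `"custom"`: `train_fun(features, labels,
#'   seed)` returns any state; `predict_fun(state, features, truth)` returns
#'   labels (the `truth` argument exists so evaluation bookkeeping can be
#'   tested against stub classifiers).
#' @return a list of class `classifier_config`.
#' @export
classifier_config <- function(name = c("original", "linear", "poly", "rbf",
                                       "rf-adaboost", "custom"),
                              budget = 25L, C = 1,
                              train_fun = NULL, predict_fun = NULL) {
  name <- match.arg(name)
  if (name == "custom" && (is.null(train_fun) || is.null(predict_fun))) {
    stopf("custom classifier needs train_fun and predict_fun")
  }
  structure(list(name = name, budget = as.integer(budget), C = C,
                 train_fun = train_fun, predict_fun = predict_fun),
            class = "classifier_config")
}

train_from_config <- function(clf, features, labels, seed) {
  switch(clf$name,
    original = train_original(features, labels, C = clf$C),
    linear = train_optimized(features, labels, svm_spec("linear"),
                             budget = clf$budget, seed = seed),
    poly = train_optimized(features, labels, svm_spec("polynomial"),
                           budget = clf$budget, seed = seed),
    rbf = train_optimized(features, labels, svm_spec("rbf"),
                          budget = clf$budget, seed = seed),
    `rf-adaboost` = train_boosted_trees(features, labels, seed = seed,
                                        optimize = TRUE, budget = clf$budget),
    custom = new_classifier("custom",
                            list(model = clf$train_fun(features, labels, seed),
                                 predict_fun = clf$predict_fun),
                            order_class_ids(unique(as.character(labels))), list())
  )
}

predict_from_config <- function(clf, model, features, truth) {
  if (model$kind == "custom") {
    model$state$predict_fun(model$state$model, features, truth)
  } else {
    stats::predict(model, features)
  }
}

# extract raw features for every image and part once; reused across repeats
precompute_raw <- function(index, parts, cfg) {
  raw <- list()
  for (part in parts) {
    raw[[part$tag]] <- lapply(seq_len(nrow(index)), function(i) {
      extract_part_raw(part, load_entry(index, i, max_side = cfg$max_side), cfg)
    })
  }
  raw
}

#' Repeated equal-split evaluation
#'
#' For each repeat: a fresh seeded per-class split, the encoder fitted on
#' training descriptors only, the classifier trained on training
#' representations, and accuracy measured on the held-out half. The report
#' aggregates mean and standard deviation over repeats and accumulates one
#' confusion matrix across all repeats.
#'
#' @param index a [dataset_index()].
#' @param enc_config an [encoder_config()]; `recipe` selects the
#'   representation.
#' @param clf_config a [classifier_config()].
#' @param recipe representation recipe string (default `"FV-SIFT"`).
#' @param repeats number of repeats (default 25).
#' @param per_class_train images per class in the training half (default 10).
#' @param seed master seed; repeat r uses split seed `seed + r`.
#' @param verbose print per-repeat progress to stderr.
#' @return an object of class `eval_report`.
#' @export
run_repeated_eval <- function(index, enc_config = encoder_config(),
                              clf_config = classifier_config("original"),
                              recipe = "FV-SIFT", repeats = 25L,
                              per_class_train = 10L, seed = 1L,
                              verbose = FALSE) {
  classes <- index_classes(index)
  parts <- parse_recipe(recipe)
  raw <- precompute_raw(index, parts, enc_config)
  conf <- matrix(0L, length(classes), length(classes),
                 dimnames = list(true = classes, predicted = classes))
  accs <- numeric(repeats)
  for (r in seq_len(repeats)) {
    t0 <- Sys.time()
    res <- tryCatch({
      plan <- make_split(index, per_class_train = per_class_train, seed = seed + r)
      tr <- split_rows(plan, index, "train")
      te <- split_rows(plan, index, "test")
      raw_rows <- function(rows) {
        stats::setNames(lapply(parts, function(p) raw[[p$tag]][rows]),
                        vapply(parts, `[[`, "", "tag"))
      }
      enc <- fit_encoder(images = NULL, recipe = recipe, cfg = enc_config,
                         seed = derive_seed(seed, r),
                         raw = lapply(raw, function(l) l[tr]))
      encode_rows <- function(rows) {
        t(vapply(rows, function(i) {
          as.numeric(encode_image(enc, raw_parts = lapply(raw, `[[`, i)))
        }, numeric(encoder_dim(enc))))
      }
      xtr <- encode_rows(tr); xte <- encode_rows(te)
      model <- train_from_config(clf_config, xtr, index$label[tr],
                                 seed = derive_seed(seed, 1000L + r))
      pred <- predict_from_config(clf_config, model, xte, index$label[te])
      list(conf = confusion_matrix(index$label[te], pred, classes))
    }, error = function(e) {
      stopf("repeat %d failed: %s", r, conditionMessage(e))
    })
    conf <- conf + res$conf
    accs[r] <- accuracy_from_confusion(res$conf)
    if (verbose) {
      message(sprintf("repeat %2d/%d: accuracy %.4f (%.1fs)", r, repeats, accs[r],
                      as.numeric(difftime(Sys.time(), t0, units = "secs"))))
    }
  }
  structure(list(per_repeat_accuracies = accs,
                 mean_accuracy = mean(accs),
                 sd_accuracy = stats::sd(accs),
                 per_class_accuracy = per_class_accuracy(conf),
                 confusion = conf,
                 config = list(recipe = recipe, encoder = unclass(enc_config),
                               classifier = clf_config$name,
                               repeats = repeats,
                               per_class_train = per_class_train,
                               seed = as.integer(seed))),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  sd_pct <- if (is.na(x$sd_accuracy)) 0 else 100 * x$sd_accuracy
  cat(sprintf("<eval_report> %s + %s: accuracy %.2f +/-%.2f%% over %d repeat(s)\n",
              x$config$recipe, x$config$classifier,
              100 * x$mean_accuracy, sd_pct, x$config$repeats))
  invisible(x)
}

#' Class-count scalability experiment
#'
#' For each subset size n and each repeat, randomly selects n classes,
#' restricts the dataset to them, and runs one seeded equal-split evaluation
#' with the given (by default "Original") classifier. All (n, repeat)
#' accuracies are recorded for [linear_extrapolation()].
#'
#' @param index a [dataset_index()].
#' @param enc_config an [encoder_config()].
#' @param clf_config a [classifier_config()] (default `"original"`).
#' @param recipe representation recipe string.
#' @param n_values subset sizes (default `seq(3, 31, by = 3)`).
#' @param repeats repeats per subset size (default 25).
#' @param per_class_train images per class in the training half.
#' @param seed master seed.
#' @param verbose print progress to stderr.
#' @return an object of class `scalability_result` with a `points`
#'   data.frame (n, rep, accuracy).
#' @export
scalability_experiment <- function(index, enc_config = encoder_config(),
                                   clf_config = classifier_config("original"),
                                   recipe = "FV-SIFT",
                                   n_values = seq(3L, 31L, by = 3L),
                                   repeats = 25L, per_class_train = 10L,
                                   seed = 1L, verbose = FALSE) {
  classes <- index_classes(index)
  if (max(n_values) > length(classes)) {
    stopf("max subset size %d exceeds the %d available classes",
          max(n_values), length(classes))
  }
  pts <- list()
  for (n in n_values) {
    for (r in seq_len(repeats)) {
      sub_seed <- derive_seed(seed, n * 1000L + r)
      chosen <- withr::with_seed(sub_seed, sample(classes, n))
      sub <- subset_index(index, chosen)
      rep_report <- run_repeated_eval(sub, enc_config, clf_config,
                                      recipe = recipe, repeats = 1L,
                                      per_class_train = per_class_train,
                                      seed = sub_seed)
      pts[[length(pts) + 1]] <- data.frame(n = n, rep = r,
                                           accuracy = rep_report$mean_accuracy)
      if (verbose) {
        message(sprintf("n = %2d rep %2d: accuracy %.4f", n, r,
                        rep_report$mean_accuracy))
      }
    }
  }
  structure(list(points = do.call(rbind, pts),
                 n_values = n_values,
                 config = list(recipe = recipe, encoder = unclass(enc_config),
                               classifier = clf_config$name, repeats = repeats,
                               per_class_train = per_class_train,
                               seed = as.integer(seed))),
            class = "scalability_result")
}

#' @export
print.scalability_result <- function(x, ...) {
  m <- stats::aggregate(accuracy ~ n, data = x$points, FUN = mean)
  cat("<scalability_result> mean accuracy by subset size:\n")
  for (i in seq_len(nrow(m))) cat(sprintf("  n = %2d: %.4f\n", m$n[i], m$accuracy[i]))
  invisible(x)
}

#' Linear extrapolation of accuracy to a larger class count
#'
#' Ordinary least squares of accuracy (in percent) on the subset size n,
#' fitted once per repeat; the reported prediction at `target_classes` is
#' the mean of the per-repeat predictions and the uncertainty their standard
#' deviation. The pooled-fit slope and intercept over all points are also
#' returned.
#'
#' @param result a [scalability_experiment()] result.
#' @param target_classes class count to extrapolate to (default 100).
#' @return list with `prediction` and `uncertainty` (percent), pooled
#'   `slope` (percent per class) and `intercept`, and the per-repeat
#'   predictions.
#' @export
linear_extrapolation <- function(result, target_classes = 100L) {
  pts <- result$points
  if (length(unique(pts$n)) < 2) stopf("need at least two distinct subset sizes")
  pts$acc_pct <- 100 * pts$accuracy
  per_rep <- vapply(sort(unique(pts$rep)), function(r) {
    d <- pts[pts$rep == r, ]
    if (length(unique(d$n)) < 2) return(NA_real_)
    fit <- stats::lm(acc_pct ~ n, data = d)
    unname(stats::predict(fit, data.frame(n = target_classes)))
  }, 0)
  per_rep <- per_rep[!is.na(per_rep)]
  pooled <- stats::lm(acc_pct ~ n, data = pts)
  list(prediction = mean(per_rep),
       uncertainty = if (length(per_rep) > 1) stats::sd(per_rep) else 0,
       slope = unname(stats::coef(pooled)[2]),
       intercept = unname(stats::coef(pooled)[1]),
       per_repeat_predictions = per_rep,
       target_classes = target_classes)
}

#' Serialize an evaluation report to deterministic JSON
#' @param report an `eval_report`.
#' @param path optional output file.
#' @return JSON string (invisibly when written to a file).
#' @export
report_to_json <- function(report, path = NULL) {
  obj <- list(
    config = report$config,
    mean_accuracy = report$mean_accuracy,
    sd_accuracy = if (is.na(report$sd_accuracy)) 0 else report$sd_accuracy,
    mean_accuracy_pct = round(100 * report$mean_accuracy, 2),
    sd_accuracy_pct = round(100 * (if (is.na(report$sd_accuracy)) 0 else report$sd_accuracy), 2),
    per_repeat_accuracies = report$per_repeat_accuracies,
    per_class_accuracy = as.list(report$per_class_accuracy),
    confusion = unname(apply(report$confusion, 1, as.integer, simplify = FALSE)),
    classes = rownames(report$confusion)
  )
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  if (is.null(path)) return(as.character(js))
  writeLines(js, path)
  invisible(as.character(js))
}
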