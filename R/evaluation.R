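# Performance evaluation: recall / true-negative-rate / macro-accuracy,
# leave-one-out CV, penalty grid search, and nested cross-validation.

#' Penalty parameter grid
#'
#' The grid of penalty values is `C = 10^x` over the given exponents,
#' by default x = -3.0, -2.75, ..., 0 (13 values). Values of C above 1 are
#' not included by default: past a certain penalty the models change little,
#' so the grid concentrates on the sparse regime.
#'
#' @param exponents Strictly increasing exponent vector.
#' @return A `c_grid`: list with `exponents` and `values`.
#' @export
c_grid <- function(exponents = seq(-3, 0, by = 0.25)) {
  stopifnot(length(exponents) >= 1, !is.unsorted(exponents, strictly = TRUE))
  structure(list(exponents = exponents, values = 10^exponents),
            class = "c_grid")
}

#' Confusion counts from true and predicted labels
#'
#' @param truth,predicted Vectors in `{-1, +1}`.
#' @return A `confusion_counts` list with `TP`, `FP`, `TN`, `FN`. Positives
#'   are the degraders (label +1).
#' @export
confusion_counts <- function(truth, predicted) {
  stopifnot(length(truth) == length(predicted),
            all(truth %in% c(-1, 1)), all(predicted %in% c(-1, 1)))
  structure(list(TP = sum(truth == 1 & predicted == 1),
                 FP = sum(truth == -1 & predicted == 1),
                 TN = sum(truth == -1 & predicted == -1),
                 FN = sum(truth == 1 & predicted == -1)),
            class = "confusion_counts")
}

#' Recall, true negative rate and macro-accuracy
#'
#' Recall = TP / (TP + FN) is the sensitivity on the degraders; the true
#' negative rate TN / (TN + FP) is the specificity on the non-degraders; the
#' macro-accuracy is their mean, which weights both classes equally despite
#' the class imbalance typical of genome collections.
#'
#' @param counts A `confusion_counts`, or a list/vector with elements
#'   `TP`, `FP`, `TN`, `FN`.
#' @return A `metric_set`: list with `recall`, `true_negative_rate`,
#'   `macro_accuracy` (raw values; see [format_metrics()] for the 2-decimal
#'   display convention).
#' @export
confusion_metrics <- function(counts) {
  counts <- as.list(counts)
  tp <- counts$TP; fp <- counts$FP; tn <- counts$TN; fn <- counts$FN
  stopifnot(all(c(tp, fp, tn, fn) >= 0))
  if (tp + fn == 0) stop("no positive samples: recall undefined")
  if (tn + fp == 0) stop("no negative samples: true negative rate undefined")
  recall <- tp / (tp + fn)
  tnr <- tn / (tn + fp)
  structure(list(recall = recall, true_negative_rate = tnr,
                 macro_accuracy = (recall + tnr) / 2),
            class = "metric_set")
}

#' @rdname confusion_metrics
#' @param metrics A `metric_set`.
#' @param digits Display rounding (default 2 decimals).
#' @export
format_metrics <- function(metrics, digits = 2) {
  vapply(metrics, function(v) round(v, digits), 0)
}

#' @export
print.metric_set <- function(x, ...) {
  m <- format_metrics(x)
  cat(sprintf("recall %.2f, TNR %.2f, macro-accuracy %.2f\n",
              m[["recall"]], m[["true_negative_rate"]], m[["macro_accuracy"]]))
  invisible(x)
}

# Fold-local preprocessing: for the frequency encoding the per-feature
# min-max scaler is fit on the training rows only and reapplied to held-out
# rows, so no information leaks across the fold boundary. Binary features are
# already in {0, 1} and are used as-is.
scale_fold <- function(train_fm, test_X = NULL) {
  if (train_fm$encoding == "frequency") {
    scaler <- fit_scaler(train_fm)
    train_X <- apply_scaler(scaler, train_fm$X)
    if (!is.null(test_X)) test_X <- apply_scaler(scaler, test_X)
  } else {
    scaler <- NULL
    train_X <- train_fm$X
  }
  list(train_X = train_X, test_X = test_X, scaler = scaler)
}

check_class_counts <- function(labels, min_per_class) {
  if (sum(labels == 1) < min_per_class || sum(labels == -1) < min_per_class)
    stop("each class needs at least ", min_per_class, " samples")
}

#' Leave-one-out cross-validation at a fixed penalty
#'
#' For each sample, a model is trained on the remaining samples (with the
#' scaler refit on those samples under the frequency encoding) and the
#' held-out sample's prediction is recorded.
#'
#' @param fm A labeled `feature_matrix` with at least two samples per class.
#' @param C Penalty parameter.
#' @param tolerance Solver tolerance passed to [svm_train()].
#' @return List with `counts` (`confusion_counts`), `metrics` (`metric_set`)
#'   and `predictions` (data frame: sample_id, truth, predicted,
#'   decision_value).
#' @export
loo_cv <- function(fm, C, tolerance = 1e-8) {
  stopifnot(inherits(fm, "feature_matrix"), !is.null(fm$labels))
  check_class_counts(fm$labels, 2)
  l <- nrow(fm$X)
  predicted <- numeric(l)
  decision <- numeric(l)
  for (i in seq_len(l)) {
    train <- subset_matrix(fm, setdiff(seq_len(l), i))
    fold <- scale_fold(train, fm$X[i, , drop = FALSE])
    model <- svm_train(fold$train_X, train$labels, C, tolerance)
    pred <- svm_predict(model, fold$test_X)
    predicted[i] <- pred$label
    decision[i] <- pred$decision_value
  }
  counts <- confusion_counts(fm$labels, predicted)
  list(counts = counts, metrics = confusion_metrics(counts),
       predictions = data.frame(sample_id = fm$sample_ids,
                                truth = as.numeric(fm$labels),
                                predicted = predicted,
                                decision_value = decision,
                                stringsAsFactors = FALSE))
}

#' Grid search over the penalty parameter
#'
#' Runs one leave-one-out cross-validation per grid value and ranks the
#' penalties by macro-accuracy (descending); ties are broken toward the
#' smaller C, preferring the sparser model.
#'
#' @param fm A labeled `feature_matrix`.
#' @param grid A [c_grid()].
#' @param tolerance Solver tolerance.
#' @return Data frame ranked best-first: `C`, `exponent`, `recall`,
#'   `true_negative_rate`, `macro_accuracy`.
#' @export
grid_search <- function(fm, grid = c_grid(), tolerance = 1e-8) {
  stopifnot(inherits(grid, "c_grid"))
  res <- lapply(seq_along(grid$values), function(k) {
    m <- loo_cv(fm, grid$values[k], tolerance)$metrics
    data.frame(C = grid$values[k], exponent = grid$exponents[k],
               recall = m$recall, true_negative_rate = m$true_negative_rate,
               macro_accuracy = m$macro_accuracy)
  })
  res <- do.call(rbind, res)
  res <- res[order(-res$macro_accuracy, res$C), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Nested cross-validation
#'
#' Unbiased accuracy estimate: the outer loop is leave-one-out; within each
#' outer fold an inner leave-one-out grid search over the remaining samples
#' picks the penalty, a model with that penalty is trained on all remaining
#' samples, and the held-out sample is predicted. The held-out sample never
#' influences its own penalty choice, scaling or training.
#'
#' @param fm A labeled `feature_matrix` with at least three samples per
#'   class.
#' @param grid A [c_grid()].
#' @param tolerance Solver tolerance.
#' @return List with `counts`, `metrics` and `predictions` (including the
#'   inner-loop `chosen_C` per outer fold).
#' @export
nested_cv <- function(fm, grid = c_grid(), tolerance = 1e-8) {
  stopifnot(inherits(fm, "feature_matrix"), !is.null(fm$labels))
  check_class_counts(fm$labels, 3)
  l <- nrow(fm$X)
  predicted <- numeric(l)
  decision <- numeric(l)
  chosen <- numeric(l)
  for (i in seq_len(l)) {
    train <- subset_matrix(fm, setdiff(seq_len(l), i))
    ranking <- grid_search(train, grid, tolerance)
    chosen[i] <- ranking$C[1]
    fold <- scale_fold(train, fm$X[i, , drop = FALSE])
    model <- svm_train(fold$train_X, train$labels, chosen[i], tolerance)
    pred <- svm_predict(model, fold$test_X)
    predicted[i] <- pred$label
    decision[i] <- pred$decision_value
  }
  counts <- confusion_counts(fm$labels, predicted)
  list(counts = counts, metrics = confusion_metrics(counts),
       predictions = data.frame(sample_id = fm$sample_ids,
                                truth = as.numeric(fm$labels),
                                predicted = predicted,
                                decision_value = decision,
                                chosen_C = chosen,
                                stringsAsFactors = FALSE))
}

#' Write an evaluation report
#'
#' JSON (raw and 2-decimal metrics, confusion counts) plus a TSV of
#' per-sample fold predictions.
#'
#' @param result Return value of [loo_cv()] or [nested_cv()].
#' @param path Base path: writes `<path>.json` and `<path>.tsv`.
#' @return `path`, invisibly.
#' @export
write_evaluation <- function(result, path) {
  jsonlite::write_json(
    list(confusion = unclass(result$counts),
         metrics = unclass(result$metrics),
         metrics_2dp = as.list(format_metrics(result$metrics))),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  write.table(result$predictions, paste0(path, ".tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}
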