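# Metrics, leave-one-out CV, penalty grid search and nested CV.

test_that("confusion metrics follow the recall/TNR/macro-accuracy formulas", {
  m <- confusion_metrics(list(TP = 18, FN = 3, TN = 79, FP = 3))
  expect_equal(m$recall, 18 / 21)
  expect_equal(m$true_negative_rate, 79 / 82)
  expect_equal(m$macro_accuracy, (18 / 21 + 79 / 82) / 2)
  expect_equal(unname(format_metrics(m)), c(0.86, 0.96, 0.91))

  perfect <- confusion_metrics(list(TP = 5, FN = 0, TN = 5, FP = 0))
  expect_equal(unlist(unclass(perfect)), c(recall = 1, true_negative_rate = 1,
                                           macro_accuracy = 1))
  expect_error(confusion_metrics(list(TP = 0, FN = 0, TN = 5, FP = 1)),
               "recall")
  expect_error(confusion_metrics(list(TP = 1, FN = 1, TN = 0, FP = 0)),
               "negative rate")
})

test_that("macro-accuracy is exactly the mean of recall and TNR", {
  set.seed(13)
  for (k in 1:10) {
    counts <- list(TP = sample(1:20, 1), FN = sample(0:5, 1),
                   TN = sample(1:50, 1), FP = sample(0:5, 1))
    m <- confusion_metrics(counts)
    expect_identical(m$macro_accuracy, (m$recall + m$true_negative_rate) / 2)
  }
})

test_that("confusion_counts tallies the four outcomes", {
  cc <- confusion_counts(truth = c(1, 1, -1, -1, 1),
                         predicted = c(1, -1, -1, 1, 1))
  expect_equal(unlist(unclass(cc)), c(TP = 2, FP = 1, TN = 1, FN = 1))
})

test_that("LOO CV is perfect on separable data and errors on tiny classes", {
  res <- loo_cv(separable_fm(), C = 1)
  expect_equal(res$metrics$macro_accuracy, 1.0)
  expect_equal(sum(unlist(unclass(res$counts))), 4)

  # a feature that encodes the label exactly stays predictive at any C >= 0.1
  fm <- toy_feature_matrix(17, l = 14, n = 6, informative = FALSE)
  fm$X[, 1] <- as.numeric(fm$labels == 1)
  fm$X[, 2] <- as.numeric(fm$labels == -1)
  for (C in c(0.1, 1))
    expect_equal(loo_cv(fm, C)$metrics$macro_accuracy, 1.0)

  lop <- feature_matrix(separable_fm()$X, "binary",
                        stats::setNames(c(1, -1, -1, -1), letters[1:4]))
  expect_error(loo_cv(lop, 1), "at least 2")
})

test_that("LOO CV equals an independently coded per-fold retraining loop", {
  fm <- toy_feature_matrix(29, l = 8, n = 5, encoding = "frequency")
  res <- loo_cv(fm, C = 0.1)

  # independent fold loop with its own min-max scaling
  predicted <- numeric(8)
  for (i in 1:8) {
    Xtr <- fm$X[-i, , drop = FALSE]
    lo <- apply(Xtr, 2, min); hi <- apply(Xtr, 2, max)
    rescale <- function(M) {
      out <- M
      for (j in seq_len(ncol(M))) {
        r <- hi[j] - lo[j]
        out[, j] <- if (r > 0) (M[, j] - lo[j]) / r else 0
      }
      out
    }
    model <- svm_train(rescale(Xtr), fm$labels[-i], C = 0.1)
    predicted[i] <- svm_predict(model, rescale(fm$X[i, , drop = FALSE]))$label
  }
  expect_equal(res$predictions$predicted, predicted)
  expect_equal(unlist(unclass(res$counts)),
               unlist(unclass(confusion_counts(fm$labels, predicted))))
})

test_that("grid search ranks by macro-accuracy with ties toward smaller C", {
  fm <- toy_feature_matrix(41, l = 10, n = 6)
  single <- grid_search(fm, c_grid(0))
  expect_equal(nrow(single), 1)
  expect_equal(single$macro_accuracy, loo_cv(fm, 1)$metrics$macro_accuracy)

  ranking <- grid_search(fm, c_grid(c(-2, -1, 0)))
  expect_setequal(ranking$C, 10^c(-2, -1, 0))        # a permutation of the grid
  expect_true(all(diff(ranking$macro_accuracy) <= 0)) # best first
  ties <- split(ranking$C, ranking$macro_accuracy)
  for (g in ties) expect_true(!is.unsorted(g))        # smaller C first on ties

  # stable under grid reordering (grids are constructed sorted)
  expect_equal(grid_search(fm, c_grid(c(-2, -1, 0))), ranking)
})

test_that("nested CV with a single-value grid degenerates to plain LOO CV", {
  fm <- toy_feature_matrix(43, l = 10, n = 6)
  nres <- nested_cv(fm, c_grid(0))
  lres <- loo_cv(fm, 1)
  expect_equal(nres$predictions$predicted, lres$predictions$predicted)
  expect_equal(unclass(nres$counts), unclass(lres$counts))
  expect_true(all(nres$predictions$chosen_C == 1))
})

test_that("nested CV is perfect on separable data and bounded on any data", {
  fm <- separable_fm()
  fm$X <- rbind(fm$X, fm$X + 0)  # 8 samples, still separable
  rownames(fm$X) <- sprintf("s%d", 1:8)
  fm <- feature_matrix(fm$X, "binary",
                       stats::setNames(rep(c(1, 1, -1, -1), 2), rownames(fm$X)))
  res <- nested_cv(fm, c_grid(c(-1, 0)))
  expect_equal(res$metrics$macro_accuracy, 1.0)
  expect_equal(sum(unlist(unclass(res$counts))), nrow(fm$X))
  expect_true(res$metrics$macro_accuracy >= 0 && res$metrics$macro_accuracy <= 1)
})

test_that("evaluation reports are written as JSON + TSV", {
  fm <- toy_feature_matrix(47, l = 8, n = 5)
  res <- loo_cv(fm, 0.5)
  base <- withr::local_tempfile()
  write_evaluation(res, base)
  rep <- jsonlite::read_json(paste0(base, ".json"), simplifyVector = TRUE)
  expect_equal(rep$confusion$TP + rep$confusion$TN +
                 rep$confusion$FP + rep$confusion$FN, 8)
  tsv <- read.delim(paste0(base, ".tsv"))
  expect_equal(nrow(tsv), 8)
})
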