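# The L1-regularized L2-loss linear SVM: objective, training via coordinate
# descent (compiled, see src/cdn_svm.cpp), prediction and serialization.

#' L1-regularized squared-hinge SVM objective
#'
#' Computes `||w||_1 + C * sum_i max(0, 1 - y_i <w, x_i>)^2`. There is no
#' intercept term: the decision function is `sign(<w, x>)`, which keeps every
#' component of the model attributable to a protein family.
#'
#' @param w Weight vector (length = number of features).
#' @param X Samples-by-features numeric matrix.
#' @param y Labels in `{-1, +1}`, one per row of `X`.
#' @param C Positive penalty parameter weighting the loss term.
#' @return The objective value (non-negative scalar).
#' @export
svm_objective <- function(w, X, y, C) {
  if (length(w) != ncol(X))
    stop("length(w) = ", length(w), " but ncol(X) = ", ncol(X))
  if (length(y) != nrow(X))
    stop("length(y) = ", length(y), " but nrow(X) = ", nrow(X))
  stopifnot(all(y %in% c(-1, 1)), C >= 0)
  margins <- y * as.numeric(X %*% w)
  sum(abs(w)) + C * sum(pmax(0, 1 - margins)^2)
}

#' Train a sparse linear SVM
#'
#' Minimizes the L1-regularized squared-hinge objective by cyclic coordinate
#' descent with Newton steps and Armijo backtracking. The problem is convex,
#' and the fixed coordinate order makes training deterministic for fixed
#' inputs. The L1 penalty drives most weights to exactly zero, so the nonzero
#' components identify the families the model discriminates on.
#'
#' @param X Samples-by-features numeric matrix (column names are taken as the
#'   family ids); values should already be encoded/scaled.
#' @param y Labels in `{-1, +1}`; both classes must be present.
#' @param C Positive penalty parameter.
#' @param tolerance Convergence tolerance on the minimum-norm subgradient
#'   (default `1e-8`).
#' @param max_iter Maximum coordinate-descent sweeps.
#' @param encoding Optional encoding tag stored on the model.
#' @return A `sparse_linear_model`: list with named weight vector `w`, `C`,
#'   `family_ids` and `encoding`.
#' @export
svm_train <- function(X, y, C, tolerance = 1e-8, max_iter = 20000L,
                      encoding = NULL) {
  X <- as.matrix(X)
  stopifnot(is.numeric(X), length(y) == nrow(X))
  if (!all(is.finite(X))) stop("X contains non-finite values")
  if (!all(y %in% c(-1, 1))) stop("y must be +1/-1")
  if (length(unique(y)) < 2)
    stop("training data must contain both classes")
  if (!is.numeric(C) || C <= 0) stop("C must be > 0")
  w <- cdn_l1_l2svm(X, as.numeric(y), C, tolerance, as.integer(max_iter))
  names(w) <- colnames(X)
  structure(list(w = w, C = C,
                 family_ids = colnames(X),
                 encoding = encoding),
            class = "sparse_linear_model")
}

#' Predict with a sparse linear SVM
#'
#' The decision value is `<w, x>`; the predicted label is +1 when it is
#' strictly positive and -1 otherwise. A decision value of exactly zero is
#' resolved to the negative class: calling an organism a degrader requires
#' positive evidence.
#'
#' @param model A `sparse_linear_model`.
#' @param x Feature vector, or matrix with one row per sample, aligned with
#'   `model$family_ids`.
#' @return Data frame with columns `label` and `decision_value`.
#' @export
svm_predict <- function(model, x) {
  stopifnot(inherits(model, "sparse_linear_model"))
  if (is.null(dim(x))) x <- matrix(x, nrow = 1, dimnames = list(NULL, names(x)))
  if (ncol(x) != length(model$w))
    stop("feature dimension ", ncol(x), " does not match model (",
         length(model$w), ")")
  if (!is.null(colnames(x)) && !is.null(model$family_ids) &&
      !identical(colnames(x), model$family_ids))
    stop("feature columns are not aligned with the model's family_ids")
  dv <- as.numeric(x %*% model$w)
  data.frame(label = ifelse(dv > 0, 1, -1), decision_value = dv)
}

#' Nonzero weights of a model
#'
#' Weights with absolute value above a small numeric floor (default `1e-9`),
#' which absorbs solver round-off when reporting sparsity.
#'
#' @param model A `sparse_linear_model`.
#' @param floor Magnitude below which a weight counts as zero.
#' @return Named vector of the nonzero weights.
#' @export
nonzero_weights <- function(model, floor = 1e-9) {
  model$w[abs(model$w) > floor]
}

#' @export
print.sparse_linear_model <- function(x, ...) {
  cat(sprintf("sparse_linear_model: %d features, %d nonzero, C = %g\n",
              length(x$w), length(nonzero_weights(x)), x$C))
  invisible(x)
}

#' Serialize a model to TSV + JSON sidecar
#'
#' Weights go to `<path>` as `family_id<TAB>weight`; penalty, encoding and any
#' scaler parameters go to `<path>.json`.
#'
#' @param model A `sparse_linear_model`.
#' @param path Weight TSV path; the sidecar is written next to it.
#' @param scaler Optional `feature_scaler` recorded in the sidecar.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path, scaler = NULL) {
  df <- data.frame(family_id = names(model$w), weight = as.numeric(model$w))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- list(C = model$C, encoding = model$encoding)
  if (!is.null(scaler))
    meta$scaler <- list(min = as.list(scaler$min), max = as.list(scaler$max))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t",
                   colClasses = c("character", "numeric"))
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  structure(list(w = stats::setNames(df$weight, df$family_id), C = meta$C,
                 family_ids = df$family_id,
                 encoding = meta$encoding),
            class = "sparse_linear_model")
}
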