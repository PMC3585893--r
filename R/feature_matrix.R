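# Feature encodings: binary presence/absence of families, or per-sample
# relative frequencies with train-derived per-feature min-max scaling.

#' Build a feature matrix from annotation profiles
#'
#' The family universe is the lexicographically ordered union of families
#' across the profiles. Under the `binary` encoding an entry is 1 iff the
#' family was annotated at least once in the sample; under the `frequency`
#' encoding it is the family count divided by the sample's total annotation
#' count, i.e. the family's relative frequency.
#'
#' @param profiles Non-empty list of `annotation_profile` objects with
#'   distinct sample ids.
#' @param encoding `"binary"` or `"frequency"`.
#' @param labels Optional named vector mapping every sample_id to +1
#'   (degrader) or -1 (non-degrader).
#' @return A `feature_matrix`: list with matrix `X` (samples x families,
#'   dimnames set), `sample_ids`, `family_ids`, `labels` (or `NULL`) and
#'   `encoding`.
#' @export
build_matrix <- function(profiles, encoding = c("binary", "frequency"),
                         labels = NULL) {
  encoding <- match.arg(encoding)
  if (inherits(profiles, "annotation_profile")) profiles <- list(profiles)
  stopifnot(length(profiles) > 0)
  sample_ids <- vapply(profiles, `[[`, "", "sample_id")
  if (anyDuplicated(sample_ids))
    stop("duplicate sample_ids: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  family_ids <- sort(unique(unlist(lapply(profiles, function(p) names(p$counts)))))

  X <- matrix(0, nrow = length(profiles), ncol = length(family_ids),
              dimnames = list(sample_ids, family_ids))
  for (k in seq_along(profiles)) {
    cts <- profiles[[k]]$counts
    if (encoding == "binary") {
      X[k, names(cts)] <- 1
    } else {
      total <- sum(cts)
      if (total == 0)
        stop("sample '", sample_ids[k],
             "' has no annotations; frequency encoding undefined")
      X[k, names(cts)] <- cts / total
    }
  }

  y <- NULL
  if (!is.null(labels)) {
    missing <- setdiff(sample_ids, names(labels))
    if (length(missing))
      stop("labels missing for samples: ", paste(missing, collapse = ", "))
    y <- as.numeric(labels[sample_ids])
    if (!all(y %in% c(-1, 1))) stop("labels must be +1 or -1")
    names(y) <- sample_ids
  }

  feature_matrix(X, encoding, y)
}

#' @rdname build_matrix
#' @param X Numeric samples-by-families matrix with dimnames.
#' @export
feature_matrix <- function(X, encoding = c("binary", "frequency"),
                           labels = NULL) {
  encoding <- match.arg(encoding)
  stopifnot(is.matrix(X), !is.null(rownames(X)), !is.null(colnames(X)))
  if (!is.null(labels)) stopifnot(all(labels %in% c(-1, 1)),
                                  length(labels) == nrow(X))
  structure(list(X = X, sample_ids = rownames(X), family_ids = colnames(X),
                 labels = labels, encoding = encoding),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("feature_matrix: %d samples x %d families (%s encoding)%s\n",
              nrow(x$X), ncol(x$X), x$encoding,
              if (is.null(x$labels)) "" else
                sprintf(", %d/%d positive", sum(x$labels == 1), length(x$labels))))
  invisible(x)
}

subset_matrix <- function(fm, rows) {
  feature_matrix(fm$X[rows, , drop = FALSE], fm$encoding,
                 if (is.null(fm$labels)) NULL else fm$labels[rows])
}

#' Per-feature min-max scaling learned on training data
#'
#' `fit_scaler` records, for every family, the minimum and maximum observed
#' across the training samples; `apply_scaler` maps a value v of family f to
#' `(v - min_f) / (max_f - min_f)`. A family that is constant on the training
#' data maps to 0. Scalers are fit on training rows only and reapplied to
#' held-out rows, so scaled held-out values may fall outside [0, 1]; they are
#' deliberately not clipped.
#'
#' @param train A `feature_matrix` of training samples.
#' @return `fit_scaler`: a `feature_scaler` (named `min`/`max` vectors).
#' @export
fit_scaler <- function(train) {
  X <- if (inherits(train, "feature_matrix")) train$X else train
  structure(list(min = apply(X, 2, min), max = apply(X, 2, max)),
            class = "feature_scaler")
}

#' @rdname fit_scaler
#' @param scaler A `feature_scaler` from [fit_scaler()].
#' @param m A `feature_matrix` (or plain matrix with colnames) whose families
#'   must all be known to the scaler.
#' @return `apply_scaler`: the input with every feature column rescaled.
#' @export
apply_scaler <- function(scaler, m) {
  stopifnot(inherits(scaler, "feature_scaler"))
  fm <- inherits(m, "feature_matrix")
  X <- if (fm) m$X else m
  unknown <- setdiff(colnames(X), names(scaler$min))
  if (length(unknown))
    stop("families unknown to the scaler: ", paste(unknown, collapse = ", "))
  rng <- scaler$max[colnames(X)] - scaler$min[colnames(X)]
  Xs <- sweep(X, 2, scaler$min[colnames(X)], "-")
  Xs <- sweep(Xs, 2, ifelse(rng > 0, rng, 1), "/")
  Xs[, rng == 0] <- 0
  if (fm) feature_matrix(Xs, m$encoding, m$labels) else Xs
}

#' Export rescaled family frequencies
#'
#' Writes (or returns) the per-sample relative frequencies of a chosen set of
#' families — the numeric content behind frequency heatmaps of selected
#' families across genomes.
#'
#' @param fm A frequency-encoded `feature_matrix`.
#' @param selected_families Families to export; must exist in `fm`.
#' @param path Optional TSV output path (first column `sample_id`).
#' @return Data frame of the selected frequencies, invisibly if written.
#' @export
export_rescaled_frequencies <- function(fm, selected_families, path = NULL) {
  stopifnot(inherits(fm, "feature_matrix"))
  unknown <- setdiff(selected_families, fm$family_ids)
  if (length(unknown))
    stop("unknown families: ", paste(unknown, collapse = ", "))
  df <- data.frame(sample_id = fm$sample_ids,
                   fm$X[, selected_families, drop = FALSE],
                   check.names = FALSE, stringsAsFactors = FALSE)
  if (!is.null(path)) {
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(df))
  }
  df
}

#' Read and write feature matrices and label tables
#'
#' Matrix TSV: header row of family ids, first column `sample_id`. Label TSV:
#' columns `sample_id` and `label` with values `+1`/`-1`.
#'
#' @param fm A `feature_matrix`.
#' @param path File path.
#' @param encoding Encoding recorded on a matrix read back.
#' @return Read functions return the parsed object; write functions return
#'   `path` invisibly.
#' @export
write_matrix <- function(fm, path) {
  df <- data.frame(sample_id = fm$sample_ids, fm$X,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix
#' @param labels Optional named label vector to attach (e.g. from
#'   [read_labels()]).
#' @export
read_matrix <- function(path, encoding = c("binary", "frequency"),
                        labels = NULL) {
  encoding <- match.arg(encoding)
  df <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                   colClasses = "character")
  X <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(X) <- "double"
  rownames(X) <- df[[1]]
  y <- NULL
  if (!is.null(labels)) {
    missing <- setdiff(rownames(X), names(labels))
    if (length(missing))
      stop("labels missing for samples: ", paste(missing, collapse = ", "))
    y <- stats::setNames(as.numeric(labels[rownames(X)]), rownames(X))
  }
  feature_matrix(X, encoding, y)
}

#' @rdname write_matrix
#' @export
read_labels <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t",
                   colClasses = c("character", "numeric"))
  if (!all(df$label %in% c(-1, 1)))
    stop("labels in ", path, " must be +1 or -1")
  stats::setNames(df$label, df$sample_id)
}

#' @rdname write_matrix
#' @export
write_labels <- function(labels, path) {
  df <- data.frame(sample_id = names(labels),
                   label = ifelse(labels > 0, "+1", "-1"))
  df <- df[order(df$sample_id), , drop = FALSE]
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
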