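# The five-model voting committee: building it from the penalty-grid ranking,
# classifying novel genomes with graded vote symbols, and selecting the
# families most distinctive of degraders by majority positive weight.

#' Build the five-model voting committee
#'
#' A leave-one-out grid search over the full labeled dataset ranks the
#' penalty values by macro-accuracy; each of the five best penalties then
#' trains one model on the entire dataset. Under the frequency encoding the
#' scaler is fit on all samples and stored for prediction time.
#'
#' @param fm A labeled `feature_matrix`.
#' @param grid A [c_grid()] with at least five values.
#' @param tolerance Solver tolerance.
#' @return An `svm_ensemble`: list with `members` (five
#'   `sparse_linear_model`s), `grid_ranking`, `scaler` (or `NULL`),
#'   `family_ids` and `encoding`.
#' @export
build_ensemble <- function(fm, grid = c_grid(), tolerance = 1e-8) {
  stopifnot(inherits(fm, "feature_matrix"), !is.null(fm$labels))
  if (length(grid$values) < 5)
    stop("the committee needs a grid of at least 5 penalty values")
  ranking <- grid_search(fm, grid, tolerance)
  top5 <- ranking$C[1:5]
  fold <- scale_fold(fm)
  members <- lapply(top5, function(C)
    svm_train(fold$train_X, fm$labels, C, tolerance, encoding = fm$encoding))
  structure(list(members = members, grid_ranking = ranking,
                 scaler = fold$scaler, family_ids = fm$family_ids,
                 encoding = fm$encoding),
            class = "svm_ensemble")
}

#' @export
print.svm_ensemble <- function(x, ...) {
  cat(sprintf("svm_ensemble: 5 members (%s encoding, %d families), C = %s\n",
              x$encoding, length(x$family_ids),
              paste(signif(vapply(x$members, `[[`, 0, "C"), 3),
                    collapse = ", ")))
  invisible(x)
}

#' Vote symbol for a committee outcome
#'
#' Graded confidence symbols over the number of positive votes out of five:
#' 5 votes `++`, 4 `+`, 2-3 `0`, 1 `-`, 0 `--`. The binary call is
#' `degrader` for >= 4 positive votes, `non-degrader` for <= 1, and
#' `ambiguous` in between, so a strong call always corresponds to a
#' near-unanimous committee.
#'
#' @param positive_votes Integer(s) in 0..5.
#' @return Character vector of symbols.
#' @export
vote_symbol <- function(positive_votes) {
  stopifnot(all(positive_votes %in% 0:5))
  c("--", "-", "0", "0", "+", "++")[positive_votes + 1]
}

#' @rdname vote_symbol
#' @export
vote_call <- function(positive_votes) {
  stopifnot(all(positive_votes %in% 0:5))
  ifelse(positive_votes >= 4, "degrader",
         ifelse(positive_votes <= 1, "non-degrader", "ambiguous"))
}

# Project a profile onto the committee's family universe: encode, drop
# families never seen in training (with a warning), scale if needed.
encode_profile <- function(ensemble, profile) {
  stopifnot(inherits(profile, "annotation_profile"))
  cts <- profile$counts
  if (ensemble$encoding == "frequency" && sum(cts) == 0)
    stop("sample '", profile$sample_id,
         "' has no annotations; frequency encoding undefined")
  known <- intersect(names(cts), ensemble$family_ids)
  if (!length(known))
    stop("sample '", profile$sample_id,
         "' shares no families with the model's training universe")
  unseen <- setdiff(names(cts), ensemble$family_ids)
  if (length(unseen))
    warning(length(unseen), " families of sample '", profile$sample_id,
            "' were not seen in training and are ignored")
  x <- stats::setNames(numeric(length(ensemble$family_ids)),
                       ensemble$family_ids)
  if (ensemble$encoding == "binary") {
    x[known] <- 1
  } else {
    x[known] <- cts[known] / sum(cts)  # relative to the sample's full total
  }
  x <- matrix(x, nrow = 1, dimnames = list(profile$sample_id,
                                           ensemble$family_ids))
  if (!is.null(ensemble$scaler)) x <- apply_scaler(ensemble$scaler, x)
  x
}

#' Classify a genome with the voting committee
#'
#' Each member predicts on the encoded, scaled profile; the number of
#' positive votes determines the symbol and the binary call (see
#' [vote_symbol()]).
#'
#' @param ensemble An `svm_ensemble`.
#' @param profile An `annotation_profile` of the query genome; it must share
#'   at least one family with the training universe.
#' @return A `vote_result`: list with `sample_id`, `positive_votes`,
#'   `symbol`, `call` and the per-member `decision_values`.
#' @export
vote <- function(ensemble, profile) {
  stopifnot(inherits(ensemble, "svm_ensemble"))
  x <- encode_profile(ensemble, profile)
  dv <- vapply(ensemble$members,
               function(m) svm_predict(m, x)$decision_value, 0)
  pos <- sum(dv > 0)
  structure(list(sample_id = profile$sample_id,
                 positive_votes = pos,
                 symbol = vote_symbol(pos),
                 call = vote_call(pos),
                 decision_values = dv),
            class = "vote_result")
}

#' @export
print.vote_result <- function(x, ...) {
  cat(sprintf("%s: %d/5 positive votes [%s] -> %s\n",
              x$sample_id, x$positive_votes, x$symbol, x$call))
  invisible(x)
}

#' Vote report over many profiles
#'
#' @param ensemble An `svm_ensemble`.
#' @param profiles List of `annotation_profile`s.
#' @param path Optional TSV output path.
#' @return Data frame: sample_id, positive_votes, symbol, call, and one
#'   decision-value column per member.
#' @export
vote_report <- function(ensemble, profiles, path = NULL) {
  if (inherits(profiles, "annotation_profile")) profiles <- list(profiles)
  rows <- lapply(profiles, function(p) {
    v <- vote(ensemble, p)
    dv <- as.list(v$decision_values)
    names(dv) <- paste0("decision_m", seq_along(dv))
    cbind(data.frame(sample_id = v$sample_id,
                     positive_votes = v$positive_votes,
                     symbol = v$symbol, call = v$call,
                     stringsAsFactors = FALSE),
          as.data.frame(dv))
  })
  df <- do.call(rbind, rows)
  df <- df[order(df$sample_id), , drop = FALSE]
  rownames(df) <- NULL
  if (!is.null(path)) {
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(df))
  }
  df
}

#' Select the families most distinctive of degraders
#'
#' A family is selected when it receives a strictly positive weight (above a
#' small numeric floor) in the majority — at least 3 of 5 — of the committee
#' members. Selected families are ranked by support (number of members with
#' positive weight), then by the mean of those positive weights, descending;
#' remaining ties break lexicographically by family id, so the ranking is
#' deterministic and invariant to member order.
#'
#' @param ensemble An `svm_ensemble`.
#' @param min_support Minimum number of members with positive weight
#'   (default 3).
#' @param weight_floor Weights at or below this magnitude count as zero.
#' @param path Optional TSV output path.
#' @return Data frame: `family_id`, `support`, `mean_positive_weight`.
#' @export
select_features <- function(ensemble, min_support = 3, weight_floor = 1e-9,
                            path = NULL) {
  stopifnot(inherits(ensemble, "svm_ensemble"))
  W <- vapply(ensemble$members, `[[`, numeric(length(ensemble$family_ids)),
              "w")  # families x members
  W <- matrix(W, ncol = length(ensemble$members),
              dimnames = list(ensemble$family_ids, NULL))
  positive <- W > weight_floor
  support <- rowSums(positive)
  sel <- support >= min_support
  mean_pos <- vapply(seq_len(nrow(W)), function(f) {
    p <- positive[f, ]
    if (any(p)) mean(W[f, p]) else 0
  }, 0)
  df <- data.frame(family_id = rownames(W)[sel],
                   support = as.integer(support[sel]),
                   mean_positive_weight = mean_pos[sel],
                   stringsAsFactors = FALSE)
  df <- df[order(-df$support, -df$mean_positive_weight, df$family_id), ,
           drop = FALSE]
  rownames(df) <- NULL
  if (!is.null(path)) {
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(df))
  }
  df
}

#' Serialize and restore a committee
#'
#' The committee is written as a single JSON file: per-member weights and
#' penalties, the family universe, the encoding, the scaler (if any) and the
#' grid ranking.
#'
#' @param ensemble An `svm_ensemble`.
#' @param path JSON file path.
#' @return `write_ensemble` returns `path` invisibly; `read_ensemble`
#'   returns the restored `svm_ensemble`.
#' @export
write_ensemble <- function(ensemble, path) {
  obj <- list(
    encoding = ensemble$encoding,
    family_ids = ensemble$family_ids,
    members = lapply(ensemble$members, function(m)
      list(C = m$C, w = as.numeric(m$w))),
    scaler = if (is.null(ensemble$scaler)) NULL else
      list(min = as.numeric(ensemble$scaler$min),
           max = as.numeric(ensemble$scaler$max)),
    grid_ranking = ensemble$grid_ranking)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_ensemble
#' @export
read_ensemble <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = TRUE)
  fam <- obj$family_ids
  members <- lapply(seq_len(nrow(obj$members)), function(k)
    structure(list(w = stats::setNames(obj$members$w[[k]], fam),
                   C = obj$members$C[k], family_ids = fam,
                   encoding = obj$encoding),
              class = "sparse_linear_model"))
  scaler <- NULL
  if (!is.null(obj$scaler) && length(obj$scaler$min))
    scaler <- structure(list(min = stats::setNames(obj$scaler$min, fam),
                             max = stats::setNames(obj$scaler$max, fam)),
                        class = "feature_scaler")
  structure(list(members = members, grid_ranking = obj$grid_ranking,
                 scaler = scaler, family_ids = fam, encoding = obj$encoding),
            class = "svm_ensemble")
}
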