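# Reading HMMER3 per-domain hit tables and turning them into per-sample
# annotation profiles (deduplicated family counts).

#' Filtering policy for profile-HMM hits
#'
#' Thresholds applied to per-domain hits before they are counted as
#' annotations. A hit is kept when its independent e-value is at most
#' `max_e_value` and its bit score is at least `min_bit_score`. Hits against
#' CAZy (dbCAN) models whose alignment spans more than
#' `cazy_long_alignment_length` positions must additionally reach an e-value
#' of at most `cazy_long_alignment_max_e`, since long, weak alignments to the
#' broad CAZy models are a known source of spurious family assignments.
#'
#' @param max_e_value Maximum per-domain independent e-value (default `1e-2`).
#' @param min_bit_score Minimum per-domain bit score (default `25`).
#' @param cazy_long_alignment_length Alignment length (aligned positions)
#'   above which the stricter CAZy e-value applies (default `100`).
#' @param cazy_long_alignment_max_e Maximum e-value for long CAZy alignments
#'   (default `1e-4`).
#' @return A `filter_policy` object (a list of the four thresholds).
#' @export
filter_policy <- function(max_e_value = 1e-2, min_bit_score = 25,
                          cazy_long_alignment_length = 100L,
                          cazy_long_alignment_max_e = 1e-4) {
  stopifnot(max_e_value > 0,
            cazy_long_alignment_max_e <= max_e_value,
            cazy_long_alignment_length >= 1)
  structure(list(max_e_value = max_e_value,
                 min_bit_score = min_bit_score,
                 cazy_long_alignment_length = as.integer(cazy_long_alignment_length),
                 cazy_long_alignment_max_e = cazy_long_alignment_max_e),
            class = "filter_policy")
}

#' Construct a table of domain hits
#'
#' Domain hits are stored as a plain data frame with one row per profile-HMM
#' match of a protein to a family.
#'
#' @param sample_id,protein_id,family_id Character vectors (recycled to a
#'   common length).
#' @param family_db `"pfam"` or `"cazy"`, per hit.
#' @param e_value Non-negative per-domain independent e-values.
#' @param bit_score Per-domain bit scores.
#' @param alignment_length Positive integer alignment lengths (aligned
#'   positions).
#' @return A data frame of class `domain_hits`.
#' @export
domain_hits <- function(sample_id, protein_id, family_id, family_db,
                        e_value, bit_score, alignment_length) {
  df <- data.frame(sample_id = as.character(sample_id),
                   protein_id = as.character(protein_id),
                   family_id = as.character(family_id),
                   family_db = as.character(family_db),
                   e_value = as.numeric(e_value),
                   bit_score = as.numeric(bit_score),
                   alignment_length = as.integer(alignment_length),
                   stringsAsFactors = FALSE)
  if (nrow(df)) {
    if (!all(df$family_db %in% c("pfam", "cazy")))
      stop("family_db must be 'pfam' or 'cazy'")
    if (any(df$e_value < 0)) stop("e_value must be non-negative")
    if (any(df$alignment_length < 1)) stop("alignment_length must be >= 1")
  }
  class(df) <- c("domain_hits", "data.frame")
  df
}

empty_hits <- function() {
  domain_hits(character(), character(), character(), character(),
              numeric(), numeric(), integer())
}

#' Parse a HMMER3 per-domain hit table (domtblout)
#'
#' Reads the whitespace-delimited per-domain tabular output of
#' `hmmscan --domtblout` (one row per domain hit, `#` comment lines). The
#' per-domain *independent* e-value column is used, as the filtering policy is
#' defined on individual domain hits; the alignment length is computed from
#' the alignment coordinate columns as `ali_to - ali_from + 1`.
#'
#' In the `hmmscan` dialect the target is the profile HMM (family) and the
#' query is the protein; `hmmsearch` output has the two swapped, which
#' `dialect = "hmmsearch"` accounts for.
#'
#' @param lines Character vector of file lines, or a file path given as a
#'   single string naming an existing file.
#' @param sample_id Sample identifier attached to every hit.
#' @param family_db `"pfam"` or `"cazy"` for all hits in the table.
#' @param dialect `"hmmscan"` (default) or `"hmmsearch"`.
#' @return A `domain_hits` data frame.
#' @export
parse_domtblout <- function(lines, sample_id, family_db = c("pfam", "cazy"),
                            dialect = c("hmmscan", "hmmsearch")) {
  family_db <- match.arg(family_db)
  dialect <- match.arg(dialect)
  if (length(lines) == 1 && !grepl("\n", lines) && file.exists(lines))
    lines <- readLines(lines)

  is_data <- !grepl("^\\s*(#|$)", lines)
  idx <- which(is_data)
  if (!length(idx)) return(empty_hits())

  parse_row <- function(line, lineno) {
    f <- strsplit(trimws(line), "\\s+")[[1]]
    if (length(f) < 22)
      stop(sprintf("domtblout line %d: expected >= 22 columns, found %d",
                   lineno, length(f)), call. = FALSE)
    num <- function(col, what) {
      v <- suppressWarnings(as.numeric(f[col]))
      if (is.na(v))
        stop(sprintf("domtblout line %d: non-numeric %s ('%s')",
                     lineno, what, f[col]), call. = FALSE)
      v
    }
    target <- f[1]; query <- f[4]
    e <- num(13, "independent e-value")
    score <- num(14, "bit score")
    ali_from <- num(18, "alignment start")
    ali_to <- num(19, "alignment end")
    if (ali_to < ali_from || ali_from < 1)
      stop(sprintf("domtblout line %d: invalid alignment coordinates %s..%s",
                   lineno, f[18], f[19]), call. = FALSE)
    list(family = if (dialect == "hmmscan") target else query,
         protein = if (dialect == "hmmscan") query else target,
         e_value = e, bit_score = score,
         alignment_length = as.integer(ali_to - ali_from + 1))
  }

  rows <- Map(parse_row, lines[idx], idx)
  domain_hits(sample_id = sample_id,
              protein_id = vapply(rows, `[[`, "", "protein"),
              family_id = vapply(rows, `[[`, "", "family"),
              family_db = family_db,
              e_value = vapply(rows, `[[`, 0, "e_value"),
              bit_score = vapply(rows, `[[`, 0, "bit_score"),
              alignment_length = vapply(rows, `[[`, 0L, "alignment_length"))
}

#' Filter domain hits by significance thresholds
#'
#' Keeps hits with `e_value <= max_e_value` and `bit_score >= min_bit_score`.
#' CAZy hits whose alignment is longer than `cazy_long_alignment_length`
#' positions are kept only if `e_value <= cazy_long_alignment_max_e`. Row
#' order is preserved; the operation is idempotent.
#'
#' @param hits A `domain_hits` data frame.
#' @param policy A [filter_policy()].
#' @return The kept subset of `hits`.
#' @export
filter_hits <- function(hits, policy = filter_policy()) {
  stopifnot(inherits(policy, "filter_policy"))
  if (!nrow(hits)) return(hits)
  keep <- hits$e_value <= policy$max_e_value &
    hits$bit_score >= policy$min_bit_score
  long_cazy <- hits$family_db == "cazy" &
    hits$alignment_length > policy$cazy_long_alignment_length
  keep[long_cazy] <- keep[long_cazy] &
    hits$e_value[long_cazy] <= policy$cazy_long_alignment_max_e
  hits[keep, , drop = FALSE]
}

#' Aggregate filtered hits into an annotation profile
#'
#' Multiple hits of the same protein against the same family count as a
#' single annotation, so the count for a family is the number of distinct
#' proteins with at least one kept hit to it.
#'
#' @param sample_id Sample identifier; all hits must carry it.
#' @param hits A `domain_hits` data frame (typically after [filter_hits()]).
#' @param family_db Database label used when `hits` is empty; otherwise
#'   inferred from the hits.
#' @return An `annotation_profile`: a list with `sample_id`, a named integer
#'   vector `counts` (families sorted lexicographically, all counts >= 1) and
#'   `family_db`.
#' @export
aggregate_profile <- function(sample_id, hits, family_db = "pfam") {
  if (nrow(hits)) {
    if (!all(hits$sample_id == sample_id))
      stop("hits contain sample_ids other than '", sample_id, "'")
    db <- unique(hits$family_db)
    if (length(db) > 1)
      stop("hits mix family databases: ", paste(db, collapse = ", "))
    family_db <- db
    pairs <- unique(hits[, c("protein_id", "family_id")])
    tab <- table(pairs$family_id)
    counts <- stats::setNames(as.integer(tab), names(tab))
    counts <- counts[order(names(counts))]
  } else {
    counts <- stats::setNames(integer(0), character(0))
  }
  annotation_profile(sample_id, counts, family_db)
}

#' @rdname aggregate_profile
#' @param counts Named non-negative integer vector of per-family annotation
#'   counts; zero entries are dropped.
#' @export
annotation_profile <- function(sample_id, counts, family_db = "pfam") {
  stopifnot(is.character(sample_id), length(sample_id) == 1)
  counts <- counts[counts > 0]
  if (length(counts)) {
    if (is.null(names(counts)))
      stop("counts must be named by family_id")
    counts <- stats::setNames(as.integer(counts), names(counts))
    counts <- counts[order(names(counts))]
  } else {
    counts <- stats::setNames(integer(0), character(0))
  }
  structure(list(sample_id = sample_id, counts = counts,
                 family_db = family_db),
            class = "annotation_profile")
}

#' @export
print.annotation_profile <- function(x, ...) {
  cat(sprintf("annotation_profile '%s' (%s): %d families, %d annotations\n",
              x$sample_id, x$family_db, length(x$counts), sum(x$counts)))
  invisible(x)
}

#' Read and write profile tables
#'
#' Profiles are exchanged as TSV with columns `sample_id`, `family_id`,
#' `count` (one row per nonzero family), sorted lexicographically by sample
#' then family for deterministic output.
#'
#' @param profiles List of `annotation_profile` objects.
#' @param path Output (or input) file path.
#' @param family_db Database label attached to profiles read back.
#' @return `write_profiles` returns `path` invisibly; `read_profiles` returns
#'   a list of `annotation_profile` objects, ordered by sample_id.
#' @export
write_profiles <- function(profiles, path) {
  if (inherits(profiles, "annotation_profile")) profiles <- list(profiles)
  rows <- do.call(rbind, lapply(profiles, function(p) {
    if (!length(p$counts))
      return(NULL)
    data.frame(sample_id = p$sample_id, family_id = names(p$counts),
               count = as.integer(p$counts), stringsAsFactors = FALSE)
  }))
  if (is.null(rows))
    rows <- data.frame(sample_id = character(), family_id = character(),
                       count = integer())
  rows <- rows[order(rows$sample_id, rows$family_id), , drop = FALSE]
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_profiles
#' @export
read_profiles <- function(path, family_db = "pfam") {
  df <- read.table(path, header = TRUE, sep = "\t",
                   colClasses = c("character", "character", "integer"))
  lapply(split(df, df$sample_id), function(s)
    annotation_profile(s$sample_id[1],
                       stats::setNames(s$count, s$family_id), family_db))
}
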