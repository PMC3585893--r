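# Seeded synthetic annotation profiles: a minority of "planted" families is
# enriched in the positive class (standing in for degradation-associated
# families such as GH5/GH6), against a background of families whose
# occurrence is independent of the phenotype.

#' Configuration for the synthetic-profile generator
#'
#' Planted families are present with probability `p_planted_pos` in positive
#' (degrader) samples and `p_planted_neg` in negative samples; background
#' families are present with probability `background_presence` in both
#' classes. Given presence, an annotation count is drawn as
#' `1 + Poisson(count_mean - 1)`, so stored counts are always at least 1.
#'
#' @param n_pos,n_neg Number of positive/negative samples (default 20/20).
#' @param n_families Total number of families (default 200).
#' @param n_planted Number of planted families (default 15; must be less
#'   than `n_families`).
#' @param p_planted_pos,p_planted_neg Presence probability of a planted
#'   family in a positive/negative sample (defaults 0.9/0.1).
#' @param background_presence Presence probability of a background family
#'   (default 0.5).
#' @param count_mean Mean annotation count given presence (default 3).
#' @param seed RNG seed (default 42).
#' @param family_db Database label stamped on the generated profiles.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_pos = 20L, n_neg = 20L, n_families = 200L,
                              n_planted = 15L, p_planted_pos = 0.9,
                              p_planted_neg = 0.1, background_presence = 0.5,
                              count_mean = 3, seed = 42L,
                              family_db = "pfam") {
  stopifnot(n_pos >= 1, n_neg >= 1, n_families >= 2, n_planted >= 1,
            p_planted_pos > p_planted_neg,
            p_planted_pos >= 0, p_planted_pos <= 1, p_planted_neg >= 0,
            background_presence >= 0, background_presence <= 1,
            count_mean >= 1)
  if (n_planted >= n_families)
    stop("n_planted must be smaller than n_families")
  structure(list(n_pos = as.integer(n_pos), n_neg = as.integer(n_neg),
                 n_families = as.integer(n_families),
                 n_planted = as.integer(n_planted),
                 p_planted_pos = p_planted_pos,
                 p_planted_neg = p_planted_neg,
                 background_presence = background_presence,
                 count_mean = count_mean, seed = as.integer(seed),
                 family_db = family_db),
            class = "simulation_config")
}

#' Generate a synthetic labeled dataset of annotation profiles
#'
#' Fully reproducible for a fixed seed: the same config yields byte-identical
#' profiles, labels and planted-family lists.
#'
#' @param config A [simulation_config()].
#' @return List with `profiles` (list of `annotation_profile`), `labels`
#'   (named vector of +1/-1) and `planted` (ids of the planted families).
#' @export
generate_dataset <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  planted <- sprintf("PLT%04d", seq_len(config$n_planted))
  background <- sprintf("BGD%04d",
                        seq_len(config$n_families - config$n_planted))
  families <- c(planted, background)
  sample_ids <- c(sprintf("pos%03d", seq_len(config$n_pos)),
                  sprintf("neg%03d", seq_len(config$n_neg)))
  labels <- stats::setNames(rep(c(1, -1), c(config$n_pos, config$n_neg)),
                            sample_ids)

  profiles <- lapply(seq_along(sample_ids), function(k) {
    p_planted <- if (labels[k] > 0) config$p_planted_pos else config$p_planted_neg
    present <- c(runif(config$n_planted) < p_planted,
                 runif(length(background)) < config$background_presence)
    cts <- stats::setNames(integer(sum(present)), families[present])
    if (length(cts))
      cts[] <- 1L + rpois(length(cts), config$count_mean - 1)
    annotation_profile(sample_ids[k], cts, config$family_db)
  })
  list(profiles = profiles, labels = labels, planted = planted)
}

# One domtblout row in the hmmscan dialect (target = family HMM, query =
# protein). Column 13 is the per-domain independent e-value, 14 the domain
# bit score, 18/19 the alignment coordinates.
domtbl_row <- function(family, protein, e_value, score, ali_from, ali_to,
                       dom_i = 1, dom_n = 1) {
  tlen <- ali_to + 10
  qlen <- ali_to + 25
  paste(family, "-", tlen, protein, "-", qlen,
        format(e_value, scientific = TRUE), format(score + 0.5, nsmall = 1), "0.1",
        dom_i, dom_n,
        format(e_value / 10, scientific = TRUE), format(e_value, scientific = TRUE),
        format(score, nsmall = 1), "0.1",
        1, ali_to - ali_from + 1, ali_from, ali_to, ali_from, ali_to + 3,
        "0.95", "synthetic hit", sep = " ")
}

#' Generate a synthetic HMMER3 per-domain table for a profile
#'
#' Emits a valid domtblout text whose parse -> filter -> aggregate round trip
#' reproduces `profile` exactly under the default [filter_policy()]. Each
#' family's first protein carries a duplicate domain hit (exercising the
#' one-annotation-per-protein rule), and decoy rows violating each filter are
#' included: an insignificant e-value, a sub-threshold bit score and — for
#' CAZy profiles — a long alignment with an e-value above the stricter
#' long-alignment cutoff. For Pfam profiles the long-alignment row is attached
#' to an already-counted protein, since the long-alignment rule applies to
#' CAZy hits only.
#'
#' @param profile An `annotation_profile`.
#' @param seed RNG seed for score jitter.
#' @param path Optional output file path.
#' @return Character vector of file lines (invisibly if written to `path`).
#' @export
generate_domtblout <- function(profile, seed = 1L, path = NULL) {
  stopifnot(inherits(profile, "annotation_profile"))
  set.seed(seed)
  sid <- profile$sample_id
  lines <- c("#                                                               --- full sequence --- -------------- this domain -------------   hmm coord   ali coord   env coord",
             "# target name        accession   tlen query name           accession   qlen   E-value  score  bias   #  of  c-Evalue  i-Evalue  score  bias  from    to  from    to  from    to  acc description of target",
             "#------------------- ---------- ----- -------------------- ---------- ----- --------- ------ ----- --- --- --------- --------- ------ ----- ----- ----- ----- ----- ----- ----- ---- ---------------------")
  fams <- names(profile$counts)
  for (f in fams) {
    k <- profile$counts[[f]]
    for (p in seq_len(k)) {
      protein <- sprintf("%s_%s_p%02d", sid, f, p)
      score <- round(40 + runif(1) * 30, 1)
      lines <- c(lines, domtbl_row(f, protein, 1e-06, score, 1, 80,
                                   1, if (p == 1) 2 else 1))
      if (p == 1) {
        # duplicate hit of the same protein to the same family: must still
        # count as one annotation
        lines <- c(lines, domtbl_row(f, protein, 1e-05, score - 5, 90, 140, 2, 2))
        if (profile$family_db == "pfam")
          # long alignment at e = 1e-3: kept for Pfam (rule is CAZy-only),
          # but a duplicate of an already-counted protein
          lines <- c(lines, domtbl_row(f, protein, 1e-03, score, 1, 120))
      }
    }
    if (f == fams[1]) {
      # decoy rows on dedicated proteins; all must be rejected by the filter
      lines <- c(lines,
                 domtbl_row(f, paste0(sid, "_decoy_evalue"), 5e-02, 50, 1, 50),
                 domtbl_row(f, paste0(sid, "_decoy_bits"), 1e-06, 10, 1, 50))
      if (profile$family_db == "cazy")
        lines <- c(lines,
                   domtbl_row(f, paste0(sid, "_decoy_longali"), 1e-03, 50, 1, 120))
    }
  }
  lines <- c(lines, "#")
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}
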