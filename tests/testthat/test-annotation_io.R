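# HMMER3 domtblout parsing, hit filtering and profile aggregation.

good_row <- function(family = "PF00001", protein = "prot1", e = 1e-5,
                     score = 30.0, from = 10, to = 59) {
  paste(family, "-", "200", protein, "-", "350",
        format(e, scientific = TRUE), score + 1, "0.1", "1", "1",
        format(e / 10, scientific = TRUE), format(e, scientific = TRUE),
        score, "0.1", "1", to - from + 1, from, to, from, to + 2,
        "0.9", "test protein")
}

test_that("parse_domtblout maps the per-domain columns and skips comments", {
  expect_identical(nrow(parse_domtblout(c("# a comment", "#", ""), "s1")), 0L)

  hits <- parse_domtblout(c("# header", good_row()), "s1")
  expect_equal(nrow(hits), 1)
  expect_equal(hits$e_value, 1e-5)
  expect_equal(hits$bit_score, 30.0)
  expect_equal(hits$alignment_length, 50L)
  expect_equal(hits$family_id, "PF00001")
  expect_equal(hits$protein_id, "prot1")
  expect_equal(hits$sample_id, "s1")
})

test_that("parse_domtblout reports malformed rows with their line number", {
  bad_score <- sub(" 30 ", " notanumber ", good_row(score = 30))
  expect_error(parse_domtblout(c("# h", good_row(), bad_score), "s1"),
               "line 3.*non-numeric")
  expect_error(parse_domtblout("too few columns", "s1"), "line 1")
  expect_error(parse_domtblout(good_row(from = 60, to = 10), "s1"),
               "alignment coordinates")
})

test_that("parse_domtblout swaps protein and family under the hmmsearch dialect", {
  hits <- parse_domtblout(good_row(family = "seqA", protein = "GH5"), "s1",
                          family_db = "cazy", dialect = "hmmsearch")
  expect_equal(hits$family_id, "GH5")
  expect_equal(hits$protein_id, "seqA")
})

test_that("filter_hits applies the e-value, bit-score and long-CAZy rules", {
  hits <- domain_hits(
    sample_id = "s1", protein_id = sprintf("p%d", 1:5),
    family_id = c("PF1", "GH5", "GH5", "PF2", "PF3"),
    family_db = c("pfam", "cazy", "cazy", "pfam", "pfam"),
    e_value = c(1e-3, 1e-3, 1e-5, 5e-2, 1e-3),
    bit_score = c(30, 30, 30, 40, 20),
    alignment_length = c(50L, 120L, 120L, 50L, 50L))
  kept <- filter_hits(hits, filter_policy())
  # pfam within thresholds kept; long cazy needs e <= 1e-4; weak e or bits drop
  expect_equal(kept$protein_id, c("p1", "p3"))
  # a long alignment does not trigger the stricter rule for pfam hits
  long_pfam <- domain_hits("s1", "p9", "PF9", "pfam", 1e-3, 30, 120L)
  expect_equal(nrow(filter_hits(long_pfam)), 1)
})

test_that("filter_hits is idempotent and preserves order", {
  set.seed(7)
  hits <- domain_hits("s1", sprintf("p%d", 1:50), sprintf("F%d", 1:50),
                      sample(c("pfam", "cazy"), 50, TRUE),
                      10^runif(50, -6, 0), runif(50, 0, 60),
                      sample(30:150, 50, TRUE))
  once <- filter_hits(hits)
  expect_identical(filter_hits(once), once)
  expect_true(all(diff(match(once$protein_id, hits$protein_id)) > 0))
})

test_that("aggregate_profile counts distinct proteins per family", {
  two_same <- domain_hits("s1", c("p1", "p1"), c("PF1", "PF1"), "pfam",
                          c(1e-5, 1e-6), c(30, 40), c(50L, 60L))
  expect_equal(aggregate_profile("s1", two_same)$counts, c(PF1 = 1L))

  two_diff <- domain_hits("s1", c("p1", "p2"), c("PF1", "PF1"), "pfam",
                          c(1e-5, 1e-6), c(30, 40), c(50L, 60L))
  expect_equal(aggregate_profile("s1", two_diff)$counts, c(PF1 = 2L))

  empty <- aggregate_profile("s1", filter_hits(domain_hits(
    "s1", "p1", "PF1", "pfam", 1, 10, 50L)))
  expect_length(empty$counts, 0)

  mixed <- domain_hits(c("s1", "s2"), c("p1", "p2"), "PF1", "pfam",
                       1e-5, 30, 50L)
  expect_error(aggregate_profile("s1", mixed), "sample_ids")
})

test_that("profile totals never exceed the number of protein-family pairs", {
  set.seed(11)
  for (rep in 1:5) {
    hits <- domain_hits("s1", sample(sprintf("p%d", 1:10), 40, TRUE),
                        sample(sprintf("F%d", 1:6), 40, TRUE), "pfam",
                        10^runif(40, -6, -3), runif(40, 25, 60),
                        sample(30:90, 40, TRUE))
    prof <- aggregate_profile("s1", filter_hits(hits))
    expect_lte(sum(prof$counts),
               nrow(unique(hits[, c("protein_id", "family_id")])))
  }
})

test_that("parse-filter-aggregate equals a brute-force recount of the records", {
  set.seed(23)
  fams <- sprintf("PF%05d", 1:8)
  lines <- character()
  records <- list()
  for (k in 1:60) {
    f <- sample(fams, 1); p <- sprintf("p%02d", sample(1:15, 1))
    e <- 10^runif(1, -8, 0); sc <- round(runif(1, 5, 60), 1)
    len <- sample(20:140, 1)
    lines <- c(lines, good_row(f, p, e, sc, 1, len))
    records[[k]] <- data.frame(family = f, protein = p, e = e, sc = sc,
                               len = len)
  }
  prof <- aggregate_profile("sx", filter_hits(parse_domtblout(lines, "sx")))

  rec <- do.call(rbind, records)
  rec <- rec[rec$e <= 1e-2 & rec$sc >= 25, , drop = FALSE]  # pfam rules only
  expected <- vapply(split(rec$protein, rec$family),
                     function(p) length(unique(p)), 0L)
  expected <- expected[expected > 0]
  expect_equal(prof$counts, expected[order(names(expected))])
})

test_that("profile TSV round-trips with deterministic row order", {
  p1 <- annotation_profile("s2", c(GH5 = 3L, CBM6 = 1L), "cazy")
  p2 <- annotation_profile("s1", c(GH10 = 2L), "cazy")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_profiles(list(p1, p2), path)
  back <- read_profiles(path, family_db = "cazy")
  expect_equal(names(back), c("s1", "s2"))  # sorted by sample
  expect_equal(back$s2$counts, c(CBM6 = 1L, GH5 = 3L))
  expect_equal(back$s1$counts, c(GH10 = 2L))
})
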