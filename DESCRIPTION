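Package: phenosvm
Title: Predicting Microbial Plant-Biomass Degraders from Protein-Family Annotations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Predicts whether a microbial (draft) genome or metagenome encodes a
    plant-biomass degrader from its Pfam domain or CAZy family annotation
    profile, and discovers the protein families most distinctive of degraders.
    Reads HMMER3 per-domain hit tables, applies significance and
    alignment-length filters, aggregates deduplicated per-sample family counts,
    and trains an ensemble of L1-regularized L2-loss linear support vector
    machines. Classifier accuracy is estimated by nested leave-one-out
    cross-validation over a grid of penalty parameters; novel genomes are
    classified by a five-model voting committee, and distinctive families are
    selected as those with positive weight in the majority of committee
    members. Includes a seeded synthetic-data generator for end-to-end testing
    without external databases, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
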