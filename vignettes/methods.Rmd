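---
title: "Sparse SVM committees for predicting plant-biomass degraders"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sparse SVM committees for predicting plant-biomass degraders}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenosvm)
```

## The model

`phenosvm` treats phenotype prediction as supervised classification of
annotation profiles. A genome or metagenome is reduced to a vector over a
universe of protein families (Pfam domains or CAZy families), and an
L1-regularized L2-loss linear SVM without intercept is trained on labeled
examples:

$$\min_w \; \lVert w \rVert_1 + C \sum_{i=1}^{l} \max\!\big(0,\, 1 - y_i\, w^\top x_i\big)^2 .$$

The squared hinge makes the loss differentiable; the L1 penalty drives most
weights to exactly zero. Both properties matter here: the nonzero positive
weights are read off as the families distinctive of degraders, so sparseness
*is* the biological output, not just a computational convenience. There is no
intercept term, which keeps every component of the decision value
$\langle w, x\rangle$ attributable to a family; a decision value of exactly
zero is resolved to the negative class, because calling an organism a
degrader should require positive evidence.

The solver (`src/cdn_svm.cpp`) is cyclic coordinate descent with Newton
steps and Armijo backtracking on the exact one-dimensional objective — the
standard algorithm for this problem class. Coordinates are visited in a
fixed order, so training is deterministic for fixed inputs. The default
convergence tolerance (`1e-8` on the minimum-norm subgradient) is far below
anything that affects a classification; the test suite verifies the solver
against an exhaustive grid-search oracle on small instances and against
closed-form solutions of one-dimensional problems.

## From HMM hits to features

Per-domain HMMER3 hit tables are filtered before counting: a hit must have
an independent e-value of at most `1e-2` and a bit score of at least 25, and
CAZy (dbCAN) hits with alignments longer than 100 aligned positions must
additionally reach an e-value of `1e-4`. Long, marginal alignments against
the broad CAZy family models are a known source of spurious assignments;
Pfam models carry curated gathering thresholds upstream, so the stricter
rule is not applied to them. Three readings of the thresholds deserve
making explicit, since they are configurable in `filter_policy()`:

* "e-value of at least `1e-2`" is implemented as e-value $\le$ `1e-2` — at
  least that *significant* — which is the only reading consistent with a
  stringency filter.
* The long-alignment cutoff is expressed in aligned positions; a
  protein-vs-HMM alignment has no nucleotide length.
* Thresholds apply per domain hit, not per sequence, because the per-domain
  table is what is being filtered; the per-domain independent e-value column
  is used for the same reason.

Multiple qualifying hits of one protein against one family count as a single
annotation, so a family's count is the number of distinct proteins carrying
it. Two encodings turn profiles into features: **binary** presence/absence,
and **frequency** — the family count divided by the sample's total
annotation count, which corrects for genome size and annotation depth. Under
the frequency encoding each feature is min-max scaled to [0, 1] using minima
and maxima observed on *training* samples only; held-out samples reuse the
training scaler and may legitimately fall outside [0, 1] (values are not
clipped, and a family constant in training maps to 0). Binary features are
already in [0, 1] and are deliberately not passed through sum-normalization
or scaling: normalizing an indicator vector by its sum would destroy the
presence/absence semantics. The family universe is fixed at training time;
prediction-time profiles are projected onto it and families never seen in
training are dropped with a warning (they carry no weight in any model). A
query profile sharing no family at all with the universe is an error rather
than a silent all-zero vector.

## Accuracy estimation

Performance is summarized by recall on the degraders, the true negative
rate on the non-degraders, and their mean, the macro-accuracy (MACC) —
appropriate because genome collections are heavily imbalanced toward
non-degraders. Both class rates must be defined, so evaluation errors out if
either class is absent.

The penalty is chosen from the grid $C = 10^x$, $x = -3.0, -2.75, \dots, 0$
(13 values). Penalties above 1 are excluded by default because model
accuracy saturates there, while the small-$C$ end of the grid covers the
very sparse regime. Ranking uses leave-one-out CV; ties in macro-accuracy
break toward the smaller $C$, preferring the sparser, more conservative
model.

Reported accuracies come from *nested* cross-validation: an outer
leave-one-out loop, with an inner leave-one-out grid search over the
remaining $l-1$ samples choosing $C$ for that fold. The inner loop is
leave-one-out rather than k-fold for determinism and because the datasets
this tool targets are small (tens of genomes). The frequency scaler is refit
inside every fold on the training rows only, so no statistic of a held-out
sample ever influences its own prediction.

## The committee and feature selection

For classifying novel genomes, a single plain leave-one-out grid search over
the full labeled dataset ranks the penalties, and the five best each train
one model on the entire dataset. A query genome receives one vote per member;
votes are summarized as graded symbols — 5 positive votes `++`, 4 `+`, 2–3
`0`, 1 `-`, 0 `--` — with the binary call *degrader* at $\ge 4$ votes,
*non-degrader* at $\le 1$, and *ambiguous* between. The mapping is symmetric
and makes a strong call require a near-unanimous committee; both the mapping
and the majority threshold are parameters.

The degradation signature is the set of families with strictly positive
weight (above a `1e-9` numeric floor that absorbs solver round-off) in at
least 3 of the 5 members. Selected families are ranked by support, then mean
positive weight, then family id, making the output deterministic and
invariant to member order.

## The synthetic-data generator

`generate_dataset()` emulates the co-occurrence structure the classifier
exploits: a minority of *planted* families is present with probability 0.9
in degraders and 0.1 in non-degraders, background families are present with
probability 0.5 independent of the class, and counts given presence are
$1 + \mathrm{Poisson}(\mu - 1)$ with $\mu = 3$, guaranteeing stored counts
of at least 1. The defaults — 20 degraders, 20 non-degraders, 200 families
of which 15 planted — are sized like a small curated genome collection.
`generate_domtblout()` renders any profile as a valid HMMER3 per-domain
table whose parse–filter–aggregate round trip reproduces the profile
exactly, including decoy rows that each violate exactly one filter rule.

What the generator does *not* emulate: phylogenetic correlation between
genomes (an optional hard mode correlating background families within the
positive class is off by default), family–family correlation within a
genome, partial genomes, and annotation noise that depends on assembly
quality. Passing tests on synthetic data therefore demonstrate protocol
correctness — leakage-free CV, faithful filtering, deterministic committees —
not field accuracy on real genome collections.

## Sparsity versus signature completeness

A structural property of L1 regularization deserves emphasis. The 15 planted
families are *redundant* indicators of the same class label, and a sparse
linear model has no incentive to carry all of them: at every grid penalty
$C \le 1$ the optimum keeps roughly half of the planted families and prunes
the rest, and the five committee members largely agree on which half. The
test suite verifies this is a property of the optimum itself, not a solver
artifact, by matching the trained objective against an exhaustive
grid-search oracle; the sparsity-monotonicity test shows the expected
growth of the selected set with $C$. Consequently majority-positive-weight
selection is precise (contamination by background families is essentially
zero in the seeded test, and every family selected with full support is a
planted one) but deliberately incomplete as an inventory of *all*
class-associated families. Users who want a fuller inventory should inspect
the union of positive weights across members, lower `min_support`, or
examine the selection across several penalties — with the understanding that
precision will drop.

## Problem sizes and numerical choices

The shipped tests and the reproduction script run at sizes chosen to keep a
full double leave-one-out loop over the 13-value grid comfortable on one
CPU: nested CV on 24 synthetic genomes with 100 families, committee training
on the default 40-genome, 200-family set, and solver-oracle comparisons on
one- and two-feature instances with at most six samples (where an exhaustive
grid over $[-5, 5]^d$ at step 0.01 is itself exact enough to certify the
optimum to `1e-3`). Degenerate inputs are rejected rather than repaired:
training with a single class, frequency-encoding a sample with zero
annotations, applying a scaler to unknown families, or voting on a profile
disjoint from the training universe are all errors with named offenders.

## Known limitations

* Labels are taken as ground truth; the method can flag suspect labels (a
  consistently misclassified genome may be mislabeled) but does not model
  label noise.
* The committee's penalties are ranked by a single plain leave-one-out run,
  so the committee's own CV accuracy is mildly optimistic; unbiased accuracy
  always comes from `nested_cv()`.
* Binary calls on draft genomes inherit the incompleteness of the bin: a
  missing region can hide exactly the families the models weight.
* The selected signature is sparse by design (see above) and its
  composition can shift between nearby penalties when families are highly
  correlated.
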