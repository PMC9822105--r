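---
title: "GOTriplet: model, metrics and synthetic benchmarks"
author: "GOTriplet authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{GOTriplet: model, metrics and synthetic benchmarks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(GOTriplet)
```

## Scope

GOTriplet predicts Gene Ontology (GO) terms for proteins from precomputed
protein language-model embeddings. The package deliberately treats the
language model as an upstream black box: an `EmbeddingBundle` is just one
numeric matrix per "view" (typically the mean-pooled outputs of the last
three hidden layers of a model such as ESM-1b, where each layer yields an
L × D per-residue matrix that `meanPool()` collapses to a D-vector). Nothing
in the package runs or trains a transformer; what it owns is everything
downstream — the metric-learning model, the predictors, the GO machinery
and the evaluation suite — plus a synthetic-data generator that makes the
whole pipeline exercisable at desk scale.

## The ontology layer

GO is a directed acyclic graph in three aspects (MF, BP, CC) with roots
GO:0003674, GO:0008150 and GO:0005575. `readOBO()` parses `[Term]` stanzas,
keeping `is_a` and (by default) `part_of` edges, dropping obsolete terms and
cross-aspect edges, and recording `alt_id` remappings. Whether `part_of`
should participate in propagation is genuinely open in common practice; we
default to including it (the GOA convention) and expose `partOf = FALSE`
for `is_a`-only graphs.

Three operations respect the hierarchy:

* **True-path propagation** (`propagateAnnotations()`): a protein annotated
  with `q` is implicitly annotated with all ancestors of `q`. The closure is
  computed once per DAG in topological order, is idempotent, and excludes
  the aspect root by default — the root is certain for every protein and
  would only inflate every evaluation metric; `includeRoot = TRUE`
  reproduces root-inclusive comparisons where needed.
* **Hierarchical post-processing** (`postprocessScores()`): prediction
  scores are made monotone along the hierarchy by
  `s(q)_post = max(s(q), max over direct children s(child)_post)`,
  evaluated children-first so one bottom-up pass reaches the fixpoint.
  Terms absent from a score matrix are implicit zeros, so a scored
  descendant can lift an unscored ancestor into the output. The operation
  is idempotent and never lowers a score.
* **Information content** (`informationContent()`):
  `IC(q) = −log2(n_q / N)` over the propagated training corpus. Terms never
  seen in training receive a ceiling of `−log2(1/(N+1))` — just above the
  IC of a singleton — rather than infinity, which keeps IC-weighted metrics
  finite. The log base (default 2, i.e. bits) is configurable.

## Functional similarity, the supervision signal

Two proteins are compared by the overlap of their propagated, root-free GO
term sets. Four interchangeable metrics are provided: F1
(`2|a∩b| / (|a|+|b|)`, the default), Jaccard, and IC-weighted versions of
both in which cardinalities become IC-sums — down-weighting agreement on
shallow, uninformative terms. "Same function" means similarity **strictly
greater** than the cutoff `c_f`; ties at the cutoff count as different,
which matters for proteins sharing only generic ancestors.

## The triplet fusion model

Architecture: each view passes through its own dense layer of width `N1`
with a shared nonlinearity (default ReLU; identity and tanh are available),
the concatenated outputs feed the fused layer `FCL_a` of width `N2` whose
activation is the **metric embedding**, and a sigmoid layer `FCL_o` maps
the embedding to per-term confidences over the candidate set Q (every term
annotated in training). Widths default to `N1 = N2 = 1024` in
`trainingConfig()`; the synthetic experiments below use 32–64 because the
toy embedding dimension is 32.

The composite objective is `Loss_t + α·Loss_c`:

* `Loss_c` — mean binary cross-entropy of the sigmoid scores against the
  propagated 0/1 labels, natural-log convention, scores clamped to
  `[1e-7, 1 − 1e-7]`.
* `Loss_t` — batch-hard triplet loss: for each anchor in a mini-batch, the
  hardest positive (same-function protein at maximum Euclidean distance)
  and hardest negative (different-function protein at minimum distance)
  form the hinge `max(d_pos_max + margin − d_neg_min, 0)`; the loss is the
  mean over anchors of the batch (anchors lacking a positive or negative
  are skipped). An anchor is never its own positive — proteins are compared
  by ID — otherwise a duplicated protein would pin `d_pos_max` at zero.

Defaults `margin = 1`, `c_f = 0.5`, `α = 1`, `K = 10` are exposed in
`trainingConfig()` and are meant to be tuned by validation Fmax, which
`trainTripletModel()` reports per epoch when given a validation split.
Optimization is plain mini-batch Adam (`lr = 1e-3`, shuffled batches of 32)
with hand-derived gradients in base R matrix code; the analytic gradients
are verified against central finite differences in the test suite.
Training is deterministic given the seed and returns the metric embeddings
and sigmoid scores for all training proteins. Repeated runs differ only by
their derived seeds, and `ensembleAverage()` takes the elementwise mean of
their score matrices — the standard way to stabilize this class of model;
`nRuns = 10` is the conventional ensemble size.

Degenerate inputs are handled explicitly: a batch with no valid anchor is
an error, a non-finite loss aborts with the epoch/batch context, pairwise
distances are floored at 1e-12 in gradient denominators, and zero-epoch
configs return the (seeded, reproducible) initialization.

## Predictors

* **Guilt-by-association** (`gbaScores()`): the K training proteins nearest
  to the query in the trained metric space vote with linearly decaying rank
  weights `w_k = 1 − (r_k − 1)/K`; the vote is weight-normalized so scores
  stay in [0, 1]. Distance ties are broken by protein ID for determinism.
* **Internal combination** (`combineInternal()`):
  `w·s_gba + (1−w)·s_saf`, default `w = 0.5` (validation-tunable).
* **Homology consensus** (`sagpScores()`): hits with e-value ≤ 1e-3, top 10
  by bitscore, voting with bitscore weights over the templates' propagated
  annotations. Queries without usable hits are *uncovered* — absent from
  the output and reported, so coverage < 1 methods are measured honestly.
* **Single-template baseline** (`blastBaselineScores()`): the classic
  community baseline — a term's score is the maximum sequence identity
  (scaled to [0, 1]) over templates carrying it.
* **Naive prior** (`ngpScores()`): training annotation frequencies,
  identical for every query; the floor any informative method must beat.
* **PPI vote** (`ppigpScores()`): confidence-weighted vote over annotated
  interaction partners.
* **Composite combination** (`combineComposite()`):
  `β·s_model + (1−β)·s_homology` with per-aspect β defaults
  0.57 / 0.60 / 0.67 (MF / BP / CC); uncovered homology queries contribute
  zero on the homology side.

Predictions are written as CAFA-style three-column text with scores to
3 decimals; scores below a floor (default 0.01) are omitted.

## Evaluation

`fmaxSweep()` sweeps a confidence cutoff `t` over `{0, 0.01, …, 1}` (or,
with `exact = TRUE`, over every distinct positive score, which makes Fmax
invariant to monotone transforms). Two pooling modes: `"micro"` pools
tp/fp/fn over proteins before computing precision/recall; `"cafa"` (the
default) averages precision over proteins with at least one prediction and
recall over all evaluated proteins. Proteins with empty truth sets are
excluded (with a warning); implicit zeros never predict. AUPR integrates
the sweep curve step-wise in the average-precision style (recall increments
times precision at decreasing thresholds); AUROC is the Mann–Whitney
statistic with average ranks over pooled (protein, term) pairs, with a
macro-per-term option. Coverage is the fraction of test proteins with any
nonzero score. `icwFmax()` repeats the sweep with IC-sums in place of
counts. Whether AUPR/AUROC should pool pairs or average per term is left
open by common usage; micro is the default, macro a flag.

For method comparison at the individual-protein level,
`friedmanNemenyi()` ranks methods within each protein, applies the Friedman
chi-square test (via `stats::friedman.test`) and the Nemenyi post-hoc test
on mean-rank differences using the studentized range distribution, clamping
post-hoc p-values to the reportable range [1e-3, 0.9]. One contract note:
a matrix whose rows are all constant has an undefined (0/0) tie-corrected
statistic and is rejected as degenerate; the "no difference" case is
represented by balanced ranks (p = 1), not by literally identical columns.
`compareRunsToFixed()` wraps the two-sided one-sample t-test used to compare
an ensemble of runs against a single fixed competitor value.

## The synthetic generator

`syntheticConfig()` defines a seeded functional-cluster world that emulates
every real input: a random rooted DAG per aspect (root = the canonical
aspect root; each new term attaches to 1–`branching` earlier terms, so the
graph is acyclic by construction, serialized to OBO), cluster-structured
annotations, multi-view Gaussian embeddings, alignment hits, PPI edges, and
random FASTA sequences for ID bookkeeping. `simulateDataset()` writes all
of them plus split lists and a JSON manifest; identical configs produce
byte-identical directories.

Design choices worth stating:

* **Anchors are functionally distinct.** Each cluster is anchored at an
  ontology leaf and annotated with the anchor's ancestor closure. Anchor
  leaves are chosen greedily to minimize pairwise functional similarity
  (depth as tie-break): if anchors shared most of their closure, every
  protein pair would exceed `c_f` and no valid triplet would exist —
  the generator must produce within-cluster similarity strictly above
  between-cluster similarity for the supervision signal to be defined.
* **Embedding geometry.** Cluster centers are i.i.d. Gaussian with standard
  deviation `signal` per dimension; each protein draws a unit-variance
  latent around its center, and each view adds independent noise
  (`viewNoise = 0.5`). The default `signal = 1.5` places clusters in the
  overlapping-but-separable regime — separation comparable to the
  within-cluster spread — which is what pooled language-model embeddings of
  functionally related proteins look like and is precisely the regime the
  triplet objective is designed for: at random initialization most anchors
  violate the margin, and training must reorganize the space. `signal = 0`
  makes embeddings exchangeable across clusters (the negative control);
  very large values make even the untrained network margin-consistent and
  the task trivial.
* **Coverage structure.** A seeded fraction (default 0.1) of proteins gets
  no alignment hits and no PPI edges, so homology- and network-based
  predictors exercise the coverage < 1 reporting path. Same-cluster hits
  draw identities from 70–95%, cross-cluster from 20–45% — disjoint ranges,
  so cluster structure is recoverable from hits alone at zero noise.
* **New-species emulation.** `novelClusterFraction` reserves whole clusters
  for the test split, emulating generalization to species absent from
  training. The default is 0: the standard fixture tests recovery under
  matched conditions, and the novel-cluster condition is exercised as its
  own experiment.
* **Label noise** (`labelNoise`) unions a random off-cluster leaf closure
  into a protein's annotation with the given probability; the default 0
  keeps the ground truth exact.

What passing on this generator shows — and what it does not: the synthetic
world has exact, complete annotations, isotropic Gaussian clusters and
cluster-consistent hits, none of which hold for real proteomes (annotation
incompleteness, heavy-tailed term frequencies, embedding anisotropy,
homology that cuts across functional clusters). Recovery here validates the
machinery (losses, gradients, kNN transfer, hierarchy handling, metrics),
not expected real-data accuracy.

## Problem sizes and numerical conventions

The bundled experiments use 200 proteins, 4 clusters, a 50-term DAG,
embedding dimension 32, hidden widths 32–64 and 10–25 epochs — sizes chosen
so the full suite and the acceptance script run in seconds on one CPU while
every code path (mini-batching, ensembling, validation monitoring) is
exercised. Other conventions: Euclidean distances floored at 1e-12 in
gradients; cross-entropy clamp 1e-7; Fmax threshold grid step 0.01;
`tmax` reported as the smallest cutoff attaining the maximum; GBA distance
ties broken lexicographically by ID; prediction files floored at 0.01 and
printed to 3 decimals.

## Known limitations

One model per GO aspect (run aspects separately; the CLI takes `--aspect`);
no GPU path — the base-R implementation is meant for desk-scale data and
method study, not 100k-protein training; no Smin/semantic-distance
evaluation or bootstrap confidence intervals; the homology and PPI
predictors consume externally produced hit/edge tables and never run an
aligner or query an interaction database themselves.
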