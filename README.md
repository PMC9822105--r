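# GOTriplet

Protein function prediction over the Gene Ontology (GO) from precomputed
protein language-model embeddings, built around triplet metric learning and
guilt-by-association annotation transfer.

## The problem and the method

Most sequenced proteins have no experimentally supported GO annotation, and
the standard computational remedies — homology transfer, interaction-network
votes, naive term frequencies — fail whenever templates or partners are
missing. GOTriplet implements a deep metric-learning predictor that needs
only per-protein embeddings from a pretrained protein language model (e.g.
the mean-pooled outputs of the model's last three layers, supplied as plain
matrices; the language model itself is never run here).

The core model is a multi-view fusion network trained with a composite
objective. Each embedding view `x_v ∈ R^D` passes through its own dense
layer (width `N1`), the three outputs are concatenated and fused by a second
dense layer `FCL_a` (width `N2`) whose output `a(x)` is the metric
embedding, and a sigmoid output layer `FCL_o` produces per-term confidence
scores `s_saf(x, q) ∈ (0, 1)` over the candidate term set `Q`. Training
minimizes

```
Loss = Loss_t + α · Loss_c
```

where `Loss_c` is the mean binary cross-entropy of `s_saf` against the
propagated 0/1 labels `y(x, q)`, and `Loss_t` is the batch-hard triplet
loss on the metric embedding:

```
Loss_t = mean_x  max( d(x, pos)_max + margin − d(x, neg)_min , 0 )
```

with `d` the Euclidean distance, `pos`/`neg` the same-/different-function
proteins in the batch, and "same function" meaning the pairwise functional
similarity (F1 overlap of propagated GO term sets, or Jaccard / IC-weighted
variants) strictly exceeds a cutoff `c_f`. An anchor is never its own
positive.

Prediction for a query is rank-weighted k-nearest-neighbour
guilt-by-association in the learned space — the K nearest training proteins
vote with weights `w_k = 1 − (r_k − 1)/K`, so
`s_gba(q) = Σ w_k I_k(q) / Σ w_k` — convexly combined with the output-layer
scores, `s = w·s_gba + (1−w)·s_saf`, optionally blended with a
bitscore-weighted homology consensus predictor
(`β·s_model + (1−β)·s_homology`, with validation-tuned `β` per aspect:
0.57 MF / 0.60 BP / 0.67 CC), and finally made hierarchy-consistent by the
bottom-up rule `s(q)_post = max(s(q), max_children s(child)_post)`.

Everything around the model is included: OBO and GAF 2.x readers, true-path
annotation propagation, information content, the CAFA-style evaluation
suite (Fmax with its optimal threshold, AUPR, AUROC, coverage, IC-weighted
Fmax, per-protein F1, Friedman/Nemenyi method comparison), the SAGP /
single-template / naive-prior / PPI-vote baselines, and a seeded
synthetic-data generator that emulates every input file the pipeline reads.

## Worked example

Simulate a benchmark, train a 3-run ensemble, predict with the composite
combination, and evaluate:

```r
library(GOTriplet)

dir <- tempfile("demo")
simulateDataset(syntheticConfig(seed = 42), dir)

ck <- file.path(dir, "checkpoints")
runTrain(dir, ck, trainingConfig(epochs = 20, N1 = 64, N2 = 64,
                                 nRuns = 3, seed = 42))

pred <- file.path(dir, "predictions.tsv")
runPredict(dir, ck, pred, composite = TRUE)
runEvaluate(dir, pred, method = "composite")
```

This prints:

```
GO evaluation (BP, cafa pooling)
  Fmax = 1.000 at t = 0.20 | AUPR = 1.000 | AUROC = 1.000 | coverage = 1.00 | ICW-Fmax = 1.000
```

i.e. on this easy high-signal fixture the trained pipeline recovers the
held-out annotations perfectly: at confidence cutoff 0.20 the protein-
averaged precision and recall are both 1, every test protein receives a
prediction (coverage 1.00), and the ranking is perfect (AUPR/AUROC 1).
The prediction file is CAFA-style three-column text:

```
P0003	GO:9000001	0.983
P0003	GO:9000002	0.947
P0003	GO:9000003	0.916
```

The same workflows are available from a shell via the bundled CLI:

```sh
Rscript inst/scripts/gotriplet simulate --out data --seed 42
Rscript inst/scripts/gotriplet train    --data data --out ck --epochs 20 --n-runs 3
Rscript inst/scripts/gotriplet predict  --data data --checkpoints ck --out pred.tsv --composite
Rscript inst/scripts/gotriplet evaluate --data data --pred pred.tsv
Rscript inst/scripts/gotriplet baseline --data data --method sagp --out sagp.tsv
```

See `vignettes/gotriplet-methods.Rmd` for the full account of the model,
its parameters and the generator's assumptions.

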