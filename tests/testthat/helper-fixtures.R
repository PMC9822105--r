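# Shared fixtures and independent oracles, built in code at test time.

# Write a small OBO file from an edge list and parse it back.
# `terms` = character ids; `edges` = data.frame(child, parent).
oboFromEdges <- function(terms, edges, namespace = "biological_process",
                         obsolete = character(0)) {
  path <- tempfile(fileext = ".obo")
  con <- file(path, "w")
  writeLines("format-version: 1.2\n", con)
  for (id in terms) {
    writeLines(c("[Term]", sprintf("id: %s", id),
                 sprintf("name: %s", id),
                 sprintf("namespace: %s", namespace)), con)
    for (p in edges$parent[edges$child == id]) {
      writeLines(sprintf("is_a: %s ! parent", p), con)
    }
    if (id %in% obsolete) writeLines("is_obsolete: true", con)
    writeLines("", con)
  }
  close(con)
  path
}

# root <- p <- q chain rooted at the canonical BP root
chainDag <- function() {
  readOBO(oboFromEdges(
    c("GO:0008150", "GO:9000001", "GO:9000002"),
    data.frame(child = c("GO:9000001", "GO:9000002"),
               parent = c("GO:0008150", "GO:9000001"))))
}

# Oracle: transitive closure by repeated parent expansion to a fixpoint.
propagateOracle <- function(terms, dag, includeRoot = FALSE) {
  repeat {
    grown <- sort(unique(c(terms, unlist(goParents(dag)[terms]))))
    if (identical(grown, sort(terms))) break
    terms <- grown
  }
  if (!includeRoot) terms <- setdiff(terms, goRoots(dag))
  sort(terms)
}

# Oracle: iterate the parent-lift rule to a fixpoint on a named score vector.
postprocessOracle <- function(s, dag) {
  repeat {
    s2 <- s
    for (q in names(s)) {
      ch <- intersect(goChildren(dag, q), names(s))
      if (length(ch)) s2[q] <- max(s[q], s[ch])
    }
    if (identical(s2, s)) break
    s <- s2
  }
  s
}

# Oracle: brute-force pooled (micro) Fmax over every distinct score value.
fmaxMicroOracle <- function(scoresList, truthList) {
  thr <- sort(unique(unlist(lapply(scoresList, unname))))
  thr <- thr[thr > 0]
  best <- 0; bestT <- NA
  for (t in thr) {
    tp <- fp <- fn <- 0
    for (p in names(truthList)) {
      s <- scoresList[[p]] %||% numeric(0)
      pred <- names(s)[s >= t]
      tp <- tp + length(intersect(pred, truthList[[p]]))
      fp <- fp + length(setdiff(pred, truthList[[p]]))
      fn <- fn + length(setdiff(truthList[[p]], pred))
    }
    pr <- if (tp + fp > 0) tp / (tp + fp) else NA
    rc <- tp / (tp + fn)
    f <- if (!is.na(pr) && pr + rc > 0) 2 * pr * rc / (pr + rc) else 0
    if (f > best) { best <- f; bestT <- t }
  }
  list(fmax = best, tmax = bestT)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Oracle: exhaustive batch-hard loss by scanning every pair per anchor.
batchHardOracle <- function(emb, sets, margin = 1,
                            simcfg = similarityConfig()) {
  ids <- rownames(emb)
  d <- as.matrix(dist(emb))
  losses <- c()
  for (i in seq_along(ids)) {
    pos <- neg <- c()
    for (j in seq_along(ids)) {
      if (ids[j] == ids[i]) next
      if (sameFunction(sets[[ids[i]]], sets[[ids[j]]], simcfg)) {
        pos <- c(pos, j)
      } else {
        neg <- c(neg, j)
      }
    }
    if (!length(pos) || !length(neg)) next
    losses <- c(losses, max(max(d[i, pos]) + margin - min(d[i, neg]), 0))
  }
  if (!length(losses)) return(NA_real_)
  mean(losses)
}

# Small deterministic clustered world shared by several tests.
tinyWorld <- function(seed = 5, ...) {
  cfg <- syntheticConfig(seed = seed, ...)
  dag <- generateDag(cfg)
  anno <- generateAnnotations(dag, cfg)
  clusters <- attr(anno, "clusters")
  list(cfg = cfg, dag = dag, anno = anno, clusters = clusters,
       bundle = generateEmbeddings(clusters, cfg),
       splits = splitProteins(clusters, cfg))
}

subsetBundle <- function(bundle, ids) {
  EmbeddingBundle(lapply(embeddingViews(bundle),
                         function(m) m[ids, , drop = FALSE]))
}

subsetAnno <- function(anno, ids) {
  GOAnnotationSet(annotations(anno)[ids], aspect = goAspect(anno),
                  propagated = isPropagated(anno))
}

# Worked per-protein F1 examples: TP/FP counts of twelve predictors on
# three benchmark proteins with 18, 14 and 13 true BP terms respectively.
# F1 follows from the counts alone: p = TP/(TP+FP), r = TP/|truth|.
caseStudyCounts <- function() {
  tab <- read.delim(text = "
method\tprotein\ttp\tfp\tf1
SAGP\tA6XMY0\t0\t0\t0.000
PPIGP\tA6XMY0\t0\t0\t0.000
NGP\tA6XMY0\t2\t16\t0.111
DeepGO\tA6XMY0\t14\t29\t0.459
FunFams\tA6XMY0\t0\t0\t0.000
DeepGOCNN\tA6XMY0\t14\t26\t0.483
DIAMONDScore\tA6XMY0\t0\t0\t0.000
TALE\tA6XMY0\t14\t5\t0.757
ATGO\tA6XMY0\t15\t0\t0.909
DeepGOPlus\tA6XMY0\t1\t2\t0.095
TALEplus\tA6XMY0\t1\t0\t0.105
ATGOplus\tA6XMY0\t11\t0\t0.759
SAGP\tE7CIP7\t8\t9\t0.516
PPIGP\tE7CIP7\t0\t0\t0.000
NGP\tE7CIP7\t4\t14\t0.250
DeepGO\tE7CIP7\t0\t20\t0.000
FunFams\tE7CIP7\t0\t14\t0.000
DeepGOCNN\tE7CIP7\t3\t9\t0.231
DIAMONDScore\tE7CIP7\t8\t9\t0.516
TALE\tE7CIP7\t10\t2\t0.769
ATGO\tE7CIP7\t14\t2\t0.933
DeepGOPlus\tE7CIP7\t8\t10\t0.500
TALEplus\tE7CIP7\t8\t9\t0.516
ATGOplus\tE7CIP7\t14\t2\t0.933
SAGP\tF4I082\t13\t8\t0.765
PPIGP\tF4I082\t3\t16\t0.187
NGP\tF4I082\t1\t17\t0.065
DeepGO\tF4I082\t2\t57\t0.056
FunFams\tF4I082\t0\t0\t0.000
DeepGOCNN\tF4I082\t1\t11\t0.080
DIAMONDScore\tF4I082\t0\t0\t0.000
TALE\tF4I082\t1\t9\t0.087
ATGO\tF4I082\t9\t7\t0.621
DeepGOPlus\tF4I082\t0\t1\t0.000
TALEplus\tF4I082\t0\t1\t0.000
ATGOplus\tF4I082\t13\t3\t0.897
", stringsAsFactors = FALSE)
  tab$truth <- c(A6XMY0 = 18L, E7CIP7 = 14L, F4I082 = 13L)[tab$protein]
  tab
}

# Build explicit term sets realizing TP/FP counts against a truth of size n.
f1FromCounts <- function(tp, fp, nTruth) {
  truth <- sprintf("GO:90000%02d", seq_len(nTruth))
  pred <- c(truth[seq_len(tp)],
            if (fp > 0) sprintf("GO:91000%02d", seq_len(fp)))
  proteinF1(pred, truth)
}

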