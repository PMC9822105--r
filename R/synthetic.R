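## Synthetic-data generator: every input the pipeline consumes (ontology,
## true-path-consistent annotations, multi-view embeddings whose geometry
## encodes functional clusters, alignment hits, PPI edges, sequences) from
## one seeded configuration, so that training, prediction and evaluation are
## exercisable at desk scale with no external downloads.

#' Configuration of the synthetic benchmark generator
#'
#' The generator emulates a functional-cluster world: proteins belong to
#' clusters anchored at ontology leaves, annotations are each anchor's
#' ancestor closure, and embeddings are drawn from cluster-specific Gaussian
#' centers so that embedding distance correlates with functional similarity
#' when `signal > 0`.
#'
#' @param nTerms number of GO terms per aspect DAG (>= 2).
#' @param branching maximum number of parents drawn per non-root term.
#' @param nProteins number of proteins.
#' @param nClusters number of functional clusters (each a distinct leaf).
#' @param dim embedding width d per view.
#' @param signal between-cluster separation relative to unit within-cluster
#'   spread; 0 makes embeddings exchangeable across clusters.
#' @param viewNoise standard deviation of the independent per-view noise
#'   added to each protein's latent embedding.
#' @param nViews number of embedding views (default 3).
#' @param labelNoise probability that a protein additionally receives the
#'   closure of a random off-cluster leaf.
#' @param orphanFraction fraction of proteins with no alignment hits and no
#'   PPI edges, to exercise coverage < 1.
#' @param novelClusterFraction fraction of clusters reserved entirely for
#'   the test split (proteins from clusters never seen in training,
#'   emulating new-species generalization). Default 0.
#' @param testFraction,validFraction protein fractions for the held-out and
#'   validation splits.
#' @param aspect GO aspect of the toy world.
#' @param seed integer seed; fully determines every generated artifact.
#' @return list of class `syntheticConfig`.
#' @export
syntheticConfig <- function(nTerms = 50, branching = 2, nProteins = 200,
                            nClusters = 4, dim = 32, signal = 1.5,
                            viewNoise = 0.5, nViews = 3, labelNoise = 0,
                            orphanFraction = 0.1, novelClusterFraction = 0,
                            testFraction = 0.25, validFraction = 0.1,
                            aspect = "BP", seed = 1L) {
  if (nTerms < 2) stop("nTerms must be >= 2", call. = FALSE)
  if (signal < 0) stop("signal must be >= 0", call. = FALSE)
  .assertNumber(labelNoise, "labelNoise", 0, 1)
  .assertNumber(novelClusterFraction, "novelClusterFraction", 0, 1)
  structure(list(nTerms = as.integer(nTerms), branching = as.integer(branching),
                 nProteins = as.integer(nProteins),
                 nClusters = as.integer(nClusters), dim = as.integer(dim),
                 signal = signal, viewNoise = viewNoise,
                 nViews = as.integer(nViews), labelNoise = labelNoise,
                 orphanFraction = orphanFraction,
                 novelClusterFraction = novelClusterFraction,
                 testFraction = testFraction, validFraction = validFraction,
                 aspect = aspect, seed = as.integer(seed)),
            class = "syntheticConfig")
}

#' Generate a random rooted GO-like DAG
#'
#' The root takes the canonical accession of the configured aspect; each
#' subsequent term attaches to 1..`branching` previously created terms, so
#' the graph is acyclic and rooted by construction.
#'
#' @param cfg a [syntheticConfig()].
#' @return A [GeneOntology-class].
#' @export
generateDag <- function(cfg = syntheticConfig()) {
  set.seed(.deriveSeed(cfg$seed, 1L))
  n <- cfg$nTerms
  ids <- c(GO_ASPECT_ROOTS[[cfg$aspect]],
           sprintf("GO:9%06d", seq_len(n - 1L)))
  parents <- vector("list", n)
  parents[[1]] <- character(0)
  for (i in seq_len(n)[-1]) {
    k <- sample(seq_len(min(cfg$branching, i - 1L)), 1L)
    parents[[i]] <- ids[sample(i - 1L, k)]
  }
  dag <- .makeOntology(ids,
                       names_ = sprintf("synthetic term %d", seq_len(n)),
                       namespaces = rep(cfg$aspect, n),
                       parents = parents)
  validObject(dag)
  dag
}

.dagLeaves <- function(dag) {
  goTerms(dag)[lengths(goChildren(dag)) == 0L]
}

#' Generate cluster-structured, true-path-consistent annotations
#'
#' Each of `nClusters` clusters is anchored at a distinct leaf (the deepest
#' available leaves are preferred); every protein is assigned a cluster and
#' annotated with its anchor's full ancestor closure (root excluded), plus,
#' with probability `labelNoise`, the closure of one random off-cluster
#' leaf. The output is propagated by construction, so
#' [propagateAnnotations()] is a no-op on it.
#'
#' @param dag a [GeneOntology-class] from [generateDag()].
#' @param cfg a [syntheticConfig()].
#' @return A propagated [GOAnnotationSet-class] with attributes `clusters`
#'   (named cluster index per protein) and `anchors` (anchor leaf per
#'   cluster).
#' @export
generateAnnotations <- function(dag, cfg = syntheticConfig()) {
  set.seed(.deriveSeed(cfg$seed, 2L))
  leaves <- .dagLeaves(dag)
  if (length(leaves) < cfg$nClusters) {
    stop(sprintf("DAG has %d leaves but %d clusters requested",
                 length(leaves), cfg$nClusters), call. = FALSE)
  }
  anc <- termAncestors(dag)
  depth <- lengths(anc[leaves])
  root <- goRoots(dag)[[cfg$aspect]]
  closure <- function(leaf) sort(setdiff(c(leaf, anc[[leaf]]), root))
  # anchors must represent distinct functions: pick deep leaves greedily,
  # each time taking the leaf least functionally similar to those chosen
  # (depth as tie-break), so between-cluster overlap stays low
  ordered <- leaves[order(-depth, leaves)]
  anchors <- ordered[1]
  simcfg <- similarityConfig("f1")
  while (length(anchors) < cfg$nClusters) {
    cand <- setdiff(ordered, anchors)
    worst <- vapply(cand, function(l) {
      max(vapply(anchors, function(a) {
        functionalSimilarity(closure(l), closure(a), simcfg)
      }, numeric(1)))
    }, numeric(1))
    anchors <- c(anchors, cand[which.min(worst)])
  }
  ids <- sprintf("P%04d", seq_len(cfg$nProteins))
  clusters <- setNames(sample(rep_len(seq_len(cfg$nClusters),
                                      cfg$nProteins)), ids)
  sets <- lapply(ids, function(p) {
    terms <- closure(anchors[[clusters[[p]]]])
    if (cfg$labelNoise > 0 && runif(1) < cfg$labelNoise) {
      extra <- sample(setdiff(leaves, anchors[[clusters[[p]]]]), 1L)
      terms <- sort(union(terms, closure(extra)))
    }
    terms
  })
  names(sets) <- ids
  out <- GOAnnotationSet(sets, aspect = cfg$aspect, propagated = TRUE)
  attr(out, "clusters") <- clusters
  attr(out, "anchors") <- anchors
  out
}

#' Generate multi-view embeddings whose geometry encodes the clusters
#'
#' Cluster centers are i.i.d. Gaussian with standard deviation `signal`;
#' each protein draws a unit-variance latent vector around its cluster
#' center, and each view is the latent vector plus independent Gaussian
#' noise of standard deviation `viewNoise`. At `signal = 0` embeddings are
#' exchangeable across clusters; at high signal nearest neighbours are
#' same-cluster.
#'
#' @param clusters named integer vector (protein -> cluster), e.g. the
#'   `clusters` attribute of [generateAnnotations()].
#' @param cfg a [syntheticConfig()].
#' @return An [EmbeddingBundle-class] with `cfg$nViews` views.
#' @export
generateEmbeddings <- function(clusters, cfg = syntheticConfig()) {
  set.seed(.deriveSeed(cfg$seed, 3L))
  d <- cfg$dim
  nc <- max(clusters)
  centers <- matrix(rnorm(nc * d, sd = cfg$signal), nc, d)
  n <- length(clusters)
  base <- centers[clusters, , drop = FALSE] + matrix(rnorm(n * d), n, d)
  views <- lapply(seq_len(cfg$nViews), function(v) {
    m <- base + matrix(rnorm(n * d, sd = cfg$viewNoise), n, d)
    rownames(m) <- names(clusters)
    m
  })
  EmbeddingBundle(views)
}

.pickOrphans <- function(ids, fraction) {
  nOrph <- floor(fraction * length(ids))
  if (nOrph > 0) sort(sample(ids, nOrph)) else character(0)
}

#' Generate an alignment-hit table reflecting the cluster structure
#'
#' Same-cluster query/template pairs get high identity (70-95%) and
#' bitscores, cross-cluster pairs low identity (20-45%); the two ranges are
#' disjoint, so at zero noise every same-cluster hit outranks every
#' cross-cluster hit. A seeded fraction of queries is left orphaned (zero
#' hits) to exercise coverage < 1.
#'
#' @param clusters named integer vector (protein -> cluster).
#' @param cfg a [syntheticConfig()].
#' @param queries query IDs (default all proteins).
#' @param templates allowed template IDs (default all proteins); a query is
#'   never its own template.
#' @return data.frame in [readAlignmentHits()] layout, with attribute
#'   `orphans`.
#' @export
generateHits <- function(clusters, cfg = syntheticConfig(), queries = NULL,
                         templates = NULL) {
  set.seed(.deriveSeed(cfg$seed, 4L))
  ids <- names(clusters)
  if (is.null(queries)) queries <- ids
  if (is.null(templates)) templates <- ids
  orphans <- .pickOrphans(queries, cfg$orphanFraction)
  rows <- list()
  for (qy in setdiff(queries, orphans)) {
    same <- setdiff(templates[clusters[templates] == clusters[[qy]]], qy)
    diff <- setdiff(templates[clusters[templates] != clusters[[qy]]], qy)
    nSame <- min(length(same), sample(2:4, 1L))
    nDiff <- min(length(diff), sample(0:2, 1L))
    pick <- c(if (nSame) sample(same, nSame) else character(0),
              if (nDiff) sample(diff, nDiff) else character(0))
    if (!length(pick)) next
    isSame <- clusters[pick] == clusters[[qy]]
    identity <- ifelse(isSame, runif(length(pick), 70, 95),
                       runif(length(pick), 20, 45))
    bitscore <- identity * 2 + runif(length(pick), 0, 5)
    evalue <- 10 ^ (-bitscore / 10)
    rows[[qy]] <- data.frame(query = qy, template = pick,
                             identity = identity, evalue = evalue,
                             bitscore = bitscore)
  }
  out <- if (length(rows)) {
    do.call(rbind, c(rows, list(make.row.names = FALSE)))
  } else {
    data.frame(query = character(0), template = character(0),
               identity = numeric(0), evalue = numeric(0),
               bitscore = numeric(0))
  }
  attr(out, "orphans") <- orphans
  out
}

#' Generate a PPI edge list drawn preferentially within clusters
#'
#' Each non-isolated protein connects to a few same-cluster partners with
#' high confidence (0.6-0.99) and occasionally to a cross-cluster partner
#' with low confidence (0.05-0.3). A seeded fraction of proteins is left
#' isolated.
#'
#' @inheritParams generateHits
#' @return data.frame in [readPpiEdges()] layout with attribute `isolated`.
#' @export
generatePpi <- function(clusters, cfg = syntheticConfig()) {
  set.seed(.deriveSeed(cfg$seed, 5L))
  ids <- names(clusters)
  isolated <- .pickOrphans(ids, cfg$orphanFraction)
  active <- setdiff(ids, isolated)
  rows <- list()
  for (qy in active) {
    same <- setdiff(active[clusters[active] == clusters[[qy]]], qy)
    diff <- setdiff(active[clusters[active] != clusters[[qy]]], qy)
    nSame <- min(length(same), sample(1:3, 1L))
    if (nSame) {
      pk <- sample(same, nSame)
      rows[[paste0(qy, ".s")]] <- data.frame(
        a = qy, b = pk, weight = runif(nSame, 0.6, 0.99))
    }
    if (length(diff) && runif(1) < 0.3) {
      pk <- sample(diff, 1L)
      rows[[paste0(qy, ".d")]] <- data.frame(
        a = qy, b = pk, weight = runif(1, 0.05, 0.3))
    }
  }
  out <- if (length(rows)) {
    do.call(rbind, c(rows, list(make.row.names = FALSE)))
  } else {
    data.frame(a = character(0), b = character(0), weight = numeric(0))
  }
  # undirected: canonicalize order and deduplicate
  flip <- out$a > out$b
  tmp <- out$a[flip]; out$a[flip] <- out$b[flip]; out$b[flip] <- tmp
  out <- out[!duplicated(out[, c("a", "b")]), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "isolated") <- isolated
  out
}

#' Split proteins into train / validation / test sets
#'
#' Random split, except that proteins of clusters reserved by
#' `novelClusterFraction` go entirely to the test split (new-species
#' emulation).
#'
#' @param clusters named integer vector (protein -> cluster).
#' @param cfg a [syntheticConfig()].
#' @return list with `train`, `valid`, `test` ID vectors.
#' @export
splitProteins <- function(clusters, cfg = syntheticConfig()) {
  set.seed(.deriveSeed(cfg$seed, 6L))
  ids <- names(clusters)
  nNovel <- floor(cfg$novelClusterFraction * max(clusters))
  novelClusters <- if (nNovel > 0) sample(max(clusters), nNovel) else integer(0)
  novel <- ids[clusters %in% novelClusters]
  rest <- sample(setdiff(ids, novel))
  nTest <- max(0L, round(cfg$testFraction * length(ids)) - length(novel))
  nValid <- round(cfg$validFraction * length(ids))
  test <- c(novel, rest[seq_len(nTest)])
  valid <- rest[nTest + seq_len(nValid)]
  train <- setdiff(rest, c(test, valid))
  list(train = sort(train), valid = sort(valid), test = sort(test))
}

.randomFasta <- function(ids, path, minLen = 60, maxLen = 120) {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  con <- file(path, "w")
  on.exit(close(con))
  for (p in ids) {
    len <- sample(minLen:maxLen, 1L)
    writeLines(c(sprintf(">%s", p),
                 paste(sample(aa, len, replace = TRUE), collapse = "")), con)
  }
  invisible(path)
}

.writeGaf <- function(anno, path) {
  a <- annotations(anno)
  aspectLetter <- c(MF = "F", BP = "P", CC = "C")[[goAspect(anno)]]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("!gaf-version: 2.2", con)
  for (p in names(a)) {
    for (term in a[[p]]) {
      writeLines(paste(c("SYN", p, p, "", term, "SYN:0000001", "IDA", "",
                         aspectLetter, "", "", "protein", "taxon:0000", "20260101",
                         "SYN", "", ""), collapse = "\t"), con)
    }
  }
  invisible(path)
}

#' Generate and write a complete synthetic dataset directory
#'
#' Produces every file the pipeline reads: `ontology.obo`, annotations as
#' GAF (`annotations.gaf`) and two-column TSV (`annotations.tsv`),
#' per-view embedding matrices under `embeddings/`, `hits.tsv`, `ppi.tsv`,
#' `sequences.fasta`, split ID lists (`train.txt`, `valid.txt`,
#' `test.txt`), cluster labels (`clusters.tsv`) and a `manifest.json`
#' recording the seed and every generator parameter.
#'
#' @param cfg a [syntheticConfig()].
#' @param dir output directory.
#' @param force overwrite an existing non-empty directory.
#' @return the dataset directory path, invisibly; the generated in-memory
#'   objects are attached as attributes (`dag`, `annotations`, `clusters`,
#'   `splits`).
#' @export
simulateDataset <- function(cfg = syntheticConfig(), dir, force = FALSE) {
  if (cfg$nProteins < 1L) stop("nProteins must be >= 1", call. = FALSE)
  if (dir.exists(dir) && length(dir(dir)) && !force) {
    stop("output directory ", dir, " is not empty (use force = TRUE)",
         call. = FALSE)
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  dag <- generateDag(cfg)
  anno <- generateAnnotations(dag, cfg)
  clusters <- attr(anno, "clusters")
  bundle <- generateEmbeddings(clusters, cfg)
  splits <- splitProteins(clusters, cfg)
  hits <- generateHits(clusters, cfg, queries = names(clusters),
                       templates = splits$train)
  ppi <- generatePpi(clusters, cfg)
  writeOBO(dag, file.path(dir, "ontology.obo"))
  .writeGaf(anno, file.path(dir, "annotations.gaf"))
  writeAnnotationsTSV(anno, file.path(dir, "annotations.tsv"))
  writeEmbeddingViews(bundle, file.path(dir, "embeddings"))
  write.table(hits, file.path(dir, "hits.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  write.table(ppi, file.path(dir, "ppi.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  .randomFasta(names(clusters), file.path(dir, "sequences.fasta"))
  for (s in names(splits)) {
    writeLines(splits[[s]], file.path(dir, paste0(s, ".txt")))
  }
  write.table(data.frame(protein = names(clusters), cluster = clusters),
              file.path(dir, "clusters.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  manifest <- c(list(generator = "GOTriplet::simulateDataset"),
                unclass(cfg))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  out <- invisible(dir)
  attr(out, "dag") <- dag
  attr(out, "annotations") <- anno
  attr(out, "clusters") <- clusters
  attr(out, "splits") <- splits
  invisible(out)
}
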