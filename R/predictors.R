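## Predictors that turn evidence into GOScoreMatrix objects: rank-weighted
## kNN guilt-by-association in the learned embedding space, the internal
## score combination, and the homology / naive / PPI baselines.

#' Guilt-by-association scores from K nearest training templates
#'
#' For each query, the K training proteins with the smallest Euclidean
#' distance to the query embedding are selected as templates (distance ties
#' broken by protein ID for determinism). The k-th ranked template carries
#' weight `w_k = 1 - (r_k - 1) / K`, and the confidence of term `q` is the
#' weight-normalized vote `sum_k w_k I_k(q) / sum_k w_k` where `I_k(q)`
#' indicates whether the template is annotated with `q`.
#'
#' @param queryEmb numeric matrix (queries x N2) of query embeddings with
#'   protein-ID rownames, from the same trained fused layer as `trainEmb`.
#' @param trainEmb numeric matrix of training-protein embeddings.
#' @param trainAnno propagated [GOAnnotationSet-class] of the training
#'   proteins.
#' @param K number of templates; must not exceed the training-set size.
#' @return A [GOScoreMatrix-class] over all training terms.
#' @export
gbaScores <- function(queryEmb, trainEmb, trainAnno, K = 10) {
  stopifnot(is(trainAnno, "GOAnnotationSet"))
  trainIds <- intersect(rownames(trainEmb), proteinIds(trainAnno))
  if (K > length(trainIds)) {
    stop(sprintf("K = %d exceeds the %d annotated training proteins",
                 K, length(trainIds)), call. = FALSE)
  }
  trainEmb <- trainEmb[trainIds, , drop = FALSE]
  sets <- annotations(trainAnno)[trainIds]
  terms <- sort(unique(unlist(sets, use.names = FALSE)))
  Itrain <- .labelMatrix(sets, terms)
  wK <- 1 - (seq_len(K) - 1) / K
  out <- matrix(0, nrow(queryEmb), length(terms),
                dimnames = list(rownames(queryEmb), terms))
  for (i in seq_len(nrow(queryEmb))) {
    d <- sqrt(colSums((t(trainEmb) - queryEmb[i, ]) ^ 2))
    o <- order(d, trainIds)[seq_len(K)]
    votes <- colSums(wK * Itrain[o, , drop = FALSE])
    out[i, ] <- votes / sum(wK)
  }
  GOScoreMatrix(out, aspect = goAspect(trainAnno))
}

#' Combine guilt-by-association and output-layer scores
#'
#' Convex elementwise combination `w * s_gba + (1 - w) * s_saf`: the final
#' internal confidence of the metric-learning predictor.
#'
#' @param sGba,sSaf [GOScoreMatrix-class] objects on the same aspect. Terms
#'   or proteins present in only one input are treated as zeros there.
#' @param w weight in `[0, 1]` on the guilt-by-association component.
#' @return A [GOScoreMatrix-class].
#' @export
combineInternal <- function(sGba, sSaf, w = 0.5) {
  .assertNumber(w, "w", 0, 1)
  .combineConvex(sGba, sSaf, w)
}

.combineConvex <- function(x, y, w) {
  stopifnot(is(x, "GOScoreMatrix"), is(y, "GOScoreMatrix"))
  if (goAspect(x) != goAspect(y)) {
    stop("cannot combine score matrices from different aspects", call. = FALSE)
  }
  mx <- scoreMatrix(x); my <- scoreMatrix(y)
  prots <- sort(union(rownames(mx), rownames(my)))
  terms <- sort(union(colnames(mx), colnames(my)))
  pad <- function(m) {
    out <- matrix(0, length(prots), length(terms),
                  dimnames = list(prots, terms))
    out[rownames(m), colnames(m)] <- m
    out
  }
  GOScoreMatrix(w * pad(mx) + (1 - w) * pad(my), aspect = goAspect(x))
}

#' Read alignment hits from an outfmt-6-style TSV
#'
#' Columns: query ID, template ID, percent identity, e-value, bitscore
#' (no header).
#'
#' @param path TSV path.
#' @return data.frame with columns `query`, `template`, `identity`,
#'   `evalue`, `bitscore`.
#' @export
readAlignmentHits <- function(path) {
  tab <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 5L) stop("hit table needs 5 columns", call. = FALSE)
  df <- data.frame(query = as.character(tab[[1]]),
                   template = as.character(tab[[2]]),
                   identity = as.numeric(tab[[3]]),
                   evalue = as.numeric(tab[[4]]),
                   bitscore = as.numeric(tab[[5]]))
  if (any(df$identity < 0 | df$identity > 100)) {
    stop("identity must be in [0, 100]", call. = FALSE)
  }
  if (any(df$evalue < 0)) stop("e-values must be >= 0", call. = FALSE)
  df
}

#' Consensus homology-transfer scores (alignment-based predictor)
#'
#' Retains, per query, the hits passing the e-value cutoff, keeps the
#' `topN` by bitscore, and scores each GO term by the bitscore-weighted
#' consensus vote `sum_i b_i I_i(q) / sum_i b_i` over the retained
#' templates' propagated annotations. Queries with no retained hit are
#' uncovered: they are absent from the returned matrix rows.
#'
#' @param hits data.frame from [readAlignmentHits()].
#' @param templateAnno propagated [GOAnnotationSet-class] of the templates.
#' @param topN maximum number of templates per query (default 10).
#' @param evalueCutoff retain hits with e-value at or below this (default
#'   1e-3).
#' @param queries optional query universe; defaults to the queries present
#'   in `hits`. Used to report uncovered proteins.
#' @return A [GOScoreMatrix-class]; uncovered queries are recorded in the
#'   `uncovered` attribute.
#' @export
sagpScores <- function(hits, templateAnno, topN = 10, evalueCutoff = 1e-3,
                       queries = NULL) {
  stopifnot(is(templateAnno, "GOAnnotationSet"))
  sets <- annotations(templateAnno)
  if (is.null(queries)) queries <- unique(hits$query)
  hits <- hits[hits$evalue <= evalueCutoff & hits$template %in% names(sets), ,
               drop = FALSE]
  terms <- sort(unique(unlist(sets, use.names = FALSE)))
  rows <- list()
  for (qy in queries) {
    h <- hits[hits$query == qy, , drop = FALSE]
    if (!nrow(h)) next
    h <- h[order(-h$bitscore, h$template), , drop = FALSE]
    h <- h[seq_len(min(topN, nrow(h))), , drop = FALSE]
    I <- .labelMatrix(sets[h$template], terms)
    rows[[qy]] <- colSums(h$bitscore * I) / sum(h$bitscore)
  }
  covered <- names(rows)
  m <- if (length(rows)) {
    do.call(rbind, rows)
  } else {
    matrix(0, 0, length(terms), dimnames = list(NULL, terms))
  }
  out <- GOScoreMatrix(m, aspect = goAspect(templateAnno))
  attr(out, "uncovered") <- setdiff(queries, covered)
  out
}

#' Single-template identity-transfer baseline scores
#'
#' The classic community-baseline homology transfer: the confidence of term
#' `q` is the maximum sequence identity (scaled to `[0, 1]`) over the
#' aligned templates annotated with `q`.
#'
#' @inheritParams sagpScores
#' @return A [GOScoreMatrix-class] with an `uncovered` attribute.
#' @export
blastBaselineScores <- function(hits, templateAnno, queries = NULL) {
  stopifnot(is(templateAnno, "GOAnnotationSet"))
  sets <- annotations(templateAnno)
  if (is.null(queries)) queries <- unique(hits$query)
  hits <- hits[hits$template %in% names(sets), , drop = FALSE]
  terms <- sort(unique(unlist(sets, use.names = FALSE)))
  rows <- list()
  for (qy in queries) {
    h <- hits[hits$query == qy, , drop = FALSE]
    if (!nrow(h)) next
    I <- .labelMatrix(sets[h$template], terms)
    rows[[qy]] <- apply(I * h$identity / 100, 2, max)
  }
  m <- if (length(rows)) {
    do.call(rbind, rows)
  } else {
    matrix(0, 0, length(terms), dimnames = list(NULL, terms))
  }
  out <- GOScoreMatrix(m, aspect = goAspect(templateAnno))
  attr(out, "uncovered") <- setdiff(queries, names(rows))
  out
}

#' Naive prior-frequency predictor
#'
#' Scores every term by its relative annotation frequency in the training
#' set, identically for every query; coverage is always 1.
#'
#' @param trainAnno propagated training [GOAnnotationSet-class].
#' @param queries protein IDs to emit rows for.
#' @return A [GOScoreMatrix-class].
#' @export
ngpScores <- function(trainAnno, queries) {
  stopifnot(is(trainAnno, "GOAnnotationSet"))
  sets <- annotations(trainAnno)
  if (!length(sets)) stop("empty training annotation set", call. = FALSE)
  N <- length(sets)
  counts <- table(unlist(sets, use.names = FALSE))
  freq <- as.numeric(counts) / N
  m <- matrix(rep(freq, each = length(queries)), nrow = length(queries),
              dimnames = list(queries, names(counts)))
  GOScoreMatrix(m, aspect = goAspect(trainAnno))
}

#' Read a protein-protein interaction edge list
#'
#' Three-column TSV: protein A, protein B, confidence weight (no header).
#' Self-loops are dropped; edges are undirected.
#'
#' @param path TSV path.
#' @return data.frame with columns `a`, `b`, `weight`.
#' @export
readPpiEdges <- function(path) {
  tab <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 3L) stop("PPI table needs 3 columns", call. = FALSE)
  df <- data.frame(a = as.character(tab[[1]]), b = as.character(tab[[2]]),
                   weight = as.numeric(tab[[3]]))
  if (any(df$weight < 0)) stop("PPI weights must be >= 0", call. = FALSE)
  df[df$a != df$b, , drop = FALSE]
}

#' Interaction-partner vote predictor
#'
#' Scores term `q` for a query by the confidence-weighted vote of its
#' annotated interaction partners, `sum_p w_p I_p(q) / sum_p w_p`. Queries
#' with no annotated partner are uncovered (absent rows).
#'
#' @param ppi data.frame from [readPpiEdges()].
#' @param partnerAnno propagated [GOAnnotationSet-class] of potential
#'   partners.
#' @param queries query universe; defaults to all proteins in `ppi`.
#' @return A [GOScoreMatrix-class] with an `uncovered` attribute.
#' @export
ppigpScores <- function(ppi, partnerAnno, queries = NULL) {
  stopifnot(is(partnerAnno, "GOAnnotationSet"))
  sets <- annotations(partnerAnno)
  if (is.null(queries)) queries <- unique(c(ppi$a, ppi$b))
  und <- rbind(data.frame(q = ppi$a, p = ppi$b, w = ppi$weight),
               data.frame(q = ppi$b, p = ppi$a, w = ppi$weight))
  und <- und[und$p %in% names(sets) & und$w > 0, , drop = FALSE]
  terms <- sort(unique(unlist(sets, use.names = FALSE)))
  rows <- list()
  for (qy in queries) {
    e <- und[und$q == qy, , drop = FALSE]
    if (!nrow(e)) next
    I <- .labelMatrix(sets[e$p], terms)
    rows[[qy]] <- colSums(e$w * I) / sum(e$w)
  }
  m <- if (length(rows)) {
    do.call(rbind, rows)
  } else {
    matrix(0, 0, length(terms), dimnames = list(NULL, terms))
  }
  out <- GOScoreMatrix(m, aspect = goAspect(partnerAnno))
  attr(out, "uncovered") <- setdiff(queries, names(rows))
  out
}

#' Default per-aspect weights for the composite combination
#'
#' Validation-tuned weights on the metric-learning component when combining
#' with homology consensus scores: 0.57 (MF), 0.60 (BP), 0.67 (CC).
#' @export
defaultCompositeBeta <- function() c(MF = 0.57, BP = 0.60, CC = 0.67)

#' Composite combination of metric-learning and homology scores
#'
#' `beta * s_model + (1 - beta) * s_homology` elementwise, with `beta`
#' resolved by the score matrices' aspect. Queries uncovered by the
#' homology predictor contribute zero on that side.
#'
#' @param sModel [GOScoreMatrix-class] from the internal predictor.
#' @param sHomology [GOScoreMatrix-class] from [sagpScores()].
#' @param beta per-aspect weight map (default [defaultCompositeBeta()]) or
#'   a single number in `[0, 1]`.
#' @return A [GOScoreMatrix-class].
#' @export
combineComposite <- function(sModel, sHomology,
                             beta = defaultCompositeBeta()) {
  b <- if (length(beta) == 1L && is.null(names(beta))) {
    beta
  } else {
    beta[[goAspect(sModel)]]
  }
  if (is.null(b) || is.na(b) || b < 0 || b > 1) {
    stop("beta must be in [0, 1] for aspect ", goAspect(sModel),
         call. = FALSE)
  }
  .combineConvex(sModel, sHomology, b)
}

#' Write predictions in the CAFA three-column submission style
#'
#' One row per (protein, term) with the confidence printed to 3 decimals;
#' scores below `floor` are omitted to keep files bounded.
#'
#' @param scores a [GOScoreMatrix-class].
#' @param path output path.
#' @param floor smallest score written (default 0.01).
#' @return `path`, invisibly.
#' @export
writePredictions <- function(scores, path, floor = 0.01) {
  m <- scoreMatrix(scores)
  idx <- which(m >= floor, arr.ind = TRUE)
  df <- data.frame(protein = rownames(m)[idx[, 1]],
                   term = colnames(m)[idx[, 2]],
                   score = sprintf("%.3f", m[idx]))
  df <- df[order(df$protein, -as.numeric(df$score), df$term), ]
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read predictions written by [writePredictions()]
#'
#' @param path three-column TSV (protein, term, score).
#' @param aspect GO aspect tag for the resulting matrix.
#' @return A [GOScoreMatrix-class].
#' @export
readPredictions <- function(path, aspect = c("BP", "MF", "CC")) {
  aspect <- match.arg(aspect)
  tab <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  byProt <- split(setNames(as.numeric(tab[[3]]), tab[[2]]),
                  as.character(tab[[1]]))
  GOScoreMatrix(byProt, aspect = aspect)
}
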