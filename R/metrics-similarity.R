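#' Configuration for protein-protein functional similarity
#'
#' @param metric similarity flavour: `"f1"` (harmonic-mean overlap,
#'   the default supervision signal for triplet mining), `"jaccard"`, or the
#'   IC-weighted variants `"weighted_f1"` / `"weighted_jaccard"` where set
#'   cardinalities are replaced by information-content sums.
#' @param icWeights named numeric IC per term (from
#'   [informationContent()]); required by the weighted metrics.
#' @param cutoff the same-function cutoff `c_f` in `[0, 1]`: two proteins
#'   share a function when their similarity is strictly larger than
#'   `cutoff`.
#' @return A list of class `similarityConfig`.
#' @export
similarityConfig <- function(metric = c("f1", "jaccard", "weighted_f1",
                                        "weighted_jaccard"),
                             icWeights = NULL, cutoff = 0.5) {
  metric <- match.arg(metric)
  .assertNumber(cutoff, "cutoff", 0, 1)
  if (startsWith(metric, "weighted") && is.null(icWeights)) {
    stop("metric '", metric, "' requires icWeights", call. = FALSE)
  }
  structure(list(metric = metric, icWeights = icWeights, cutoff = cutoff),
            class = "similarityConfig")
}

#' Per-protein F1 between a predicted and a ground-truth term set
#'
#' Precision is the fraction of predicted terms that are correct, recall the
#' fraction of true terms recovered, and F1 their harmonic mean. Both sets
#' are expected to be propagated with the aspect root excluded. An empty
#' truth set leaves recall undefined and is an error; an empty prediction or
#' an empty intersection gives F1 = 0.
#'
#' @param pred character vector of predicted GO accessions.
#' @param truth character vector of experimentally annotated accessions.
#' @return F1 in `[0, 1]`.
#' @examples
#' proteinF1(pred = paste0("t", 1:15), truth = paste0("t", 1:18))  # 0.909
#' @export
proteinF1 <- function(pred, truth) {
  truth <- unique(truth)
  if (!length(truth)) stop("empty truth set: recall undefined", call. = FALSE)
  pred <- unique(pred)
  if (!length(pred)) return(0)
  tp <- length(intersect(pred, truth))
  if (tp == 0L) return(0)
  p <- tp / length(pred)
  r <- tp / length(truth)
  2 * p * r / (p + r)
}

.icSum <- function(terms, ic) {
  if (!length(terms)) return(0)
  sum(.icLookup(ic, terms, warnMissing = FALSE))
}

#' Functional similarity between two proteins' GO term sets
#'
#' The symmetric overlap measure used to label triplet-training pairs as
#' same- or different-function. `"f1"` is `2|a n b| / (|a| + |b|)`;
#' `"jaccard"` is `|a n b| / |a u b|`; the weighted variants replace each
#' cardinality with the IC-sum of the corresponding set. Two empty sets have
#' similarity 0.
#'
#' @param a,b character vectors of (propagated, root-free) GO accessions.
#' @param cfg a [similarityConfig()].
#' @return Similarity in `[0, 1]`.
#' @examples
#' functionalSimilarity(c("x", "y", "z"), c("y", "z", "u", "v"),
#'                      similarityConfig("f1"))  # 4/7
#' @export
functionalSimilarity <- function(a, b, cfg = similarityConfig()) {
  stopifnot(inherits(cfg, "similarityConfig"))
  a <- unique(a); b <- unique(b)
  if (!length(a) && !length(b)) return(0)
  i <- intersect(a, b)
  switch(cfg$metric,
    f1 = 2 * length(i) / (length(a) + length(b)),
    jaccard = length(i) / length(union(a, b)),
    weighted_f1 = {
      den <- .icSum(a, cfg$icWeights) + .icSum(b, cfg$icWeights)
      if (den == 0) 0 else 2 * .icSum(i, cfg$icWeights) / den
    },
    weighted_jaccard = {
      den <- .icSum(union(a, b), cfg$icWeights)
      if (den == 0) 0 else .icSum(i, cfg$icWeights) / den
    }
  )
}

#' Do two proteins share the same function?
#'
#' `TRUE` when the functional similarity is strictly larger than the cutoff
#' `c_f` in `cfg` (similarity exactly at the cutoff is "different").
#'
#' @inheritParams functionalSimilarity
#' @return logical.
#' @export
sameFunction <- function(a, b, cfg = similarityConfig()) {
  functionalSimilarity(a, b, cfg) > cfg$cutoff
}

#' Pairwise functional-similarity matrix
#'
#' @param anno a propagated [GOAnnotationSet-class].
#' @param cfg a [similarityConfig()].
#' @return symmetric numeric matrix (proteins x proteins) of similarities.
#' @export
similarityMatrix <- function(anno, cfg = similarityConfig()) {
  a <- annotations(anno)
  n <- length(a)
  ids <- names(a)
  m <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) {
    m[i, i] <- functionalSimilarity(a[[i]], a[[i]], cfg)
    for (j in seq_len(i - 1L)) {
      s <- functionalSimilarity(a[[i]], a[[j]], cfg)
      m[i, j] <- s
      m[j, i] <- s
    }
  }
  m
}
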