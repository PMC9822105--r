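#' @include AllGenerics.R
#' @import methods
#' @importFrom stats runif rnorm setNames p.adjust friedman.test ptukey
#' @importFrom utils read.delim write.table head
NULL

GO_ASPECTS <- c("MF", "BP", "CC")

GO_ASPECT_ROOTS <- c(
  MF = "GO:0003674",
  BP = "GO:0008150",
  CC = "GO:0005575"
)

.isGoAccession <- function(x) grepl("^GO:[0-9]{7}$", x)

#' GeneOntology: a parsed GO directed acyclic graph
#'
#' Holds the term set of one or more GO aspects with their `is_a` (and,
#' optionally, `part_of`) parent edges, the per-aspect root accessions, and
#' an `alt_id` remapping table. The graph is validated to be acyclic and
#' aspect-consistent: every parent of a term belongs to the same aspect, and
#' every non-root term can reach its aspect root.
#'
#' @slot termIds character vector of GO accessions (`GO:` + 7 digits).
#' @slot termName named character, free-text name per accession.
#' @slot namespace named character, one of `"MF"`, `"BP"`, `"CC"` per term.
#' @slot parents named list, character vector of parent accessions per term.
#' @slot children named list, inverse of `parents`.
#' @slot roots named character mapping aspect to its root accession.
#' @slot altIds named character mapping secondary accessions to canonical ones.
#'
#' @seealso [readOBO()], [generateDag()], [propagateAnnotations()]
#' @export
setClass("GeneOntology",
  representation(
    termIds = "character",
    termName = "character",
    namespace = "character",
    parents = "list",
    children = "list",
    roots = "character",
    altIds = "character"
  )
)

setValidity("GeneOntology", function(object) {
  ids <- object@termIds
  if (anyDuplicated(ids)) return("duplicated term accessions")
  if (!all(.isGoAccession(ids))) {
    bad <- ids[!.isGoAccession(ids)]
    return(sprintf("malformed GO accession(s): %s", paste(head(bad, 3), collapse = ", ")))
  }
  if (!all(object@namespace[ids] %in% GO_ASPECTS)) {
    return("namespace must be one of MF/BP/CC for every term")
  }
  for (id in ids) {
    ps <- object@parents[[id]]
    if (id %in% ps) return(sprintf("term %s is its own parent", id))
    if (!all(ps %in% ids)) return(sprintf("parent of %s missing from the term set", id))
    if (length(ps) && !all(object@namespace[ps] == object@namespace[[id]])) {
      return(sprintf("cross-aspect parent edge at %s", id))
    }
  }
  if (length(ids)) {
    g <- .ontologyGraph(object)
    if (!igraph::is_dag(g)) return("parent graph contains a cycle")
  }
  TRUE
})

.ontologyGraph <- function(dag) {
  # edges child -> parent; topological order then lists children first
  edges <- unlist(lapply(dag@termIds, function(id) {
    ps <- dag@parents[[id]]
    if (length(ps)) rbind(id, ps) else NULL
  }), use.names = FALSE)
  g <- igraph::make_empty_graph(directed = TRUE) +
    igraph::vertices(dag@termIds)
  if (length(edges)) g <- g + igraph::edges(edges)
  g
}

#' GOAnnotationSet: protein-to-GO-term assignments for one aspect
#'
#' @slot annotations named list; per protein ID, a character vector of GO
#'   accessions (all of one aspect).
#' @slot aspect `"MF"`, `"BP"` or `"CC"`.
#' @slot propagated logical; `TRUE` once the set is closed under the parent
#'   relation (true-path rule) up to, and by default excluding, the aspect
#'   root.
#' @export
setClass("GOAnnotationSet",
  representation(
    annotations = "list",
    aspect = "character",
    propagated = "logical"
  ),
  prototype(propagated = FALSE)
)

setValidity("GOAnnotationSet", function(object) {
  if (length(object@aspect) != 1L || !object@aspect %in% GO_ASPECTS) {
    return("aspect must be a single value in MF/BP/CC")
  }
  if (length(object@annotations)) {
    if (is.null(names(object@annotations)) || any(names(object@annotations) == "")) {
      return("annotations must be named by protein ID")
    }
    if (anyDuplicated(names(object@annotations))) return("duplicated protein IDs")
    ok <- vapply(object@annotations, is.character, logical(1))
    if (!all(ok)) return("each annotation entry must be a character vector")
  }
  if (length(object@propagated) != 1L) return("propagated must be a scalar flag")
  TRUE
})

#' EmbeddingBundle: per-protein vectors from several language-model layers
#'
#' Stores one numeric matrix per view (layer), rows keyed by protein ID and
#' columns the embedding dimension D. All views share the same proteins and
#' the same D; values must be finite. The bundle is the sole interface to
#' upstream language models: embeddings are consumed as data, never computed
#' here.
#'
#' @slot views list of numeric matrices (proteins x D), identical dimnames.
#' @export
setClass("EmbeddingBundle", representation(views = "list"))

setValidity("EmbeddingBundle", function(object) {
  v <- object@views
  if (!length(v)) return("at least one view is required")
  if (!all(vapply(v, is.matrix, logical(1)))) return("views must be matrices")
  ids <- rownames(v[[1]])
  if (is.null(ids)) return("view matrices must have protein IDs as rownames")
  for (m in v) {
    if (!identical(rownames(m), ids)) return("views disagree on protein IDs/order")
    if (ncol(m) != ncol(v[[1]])) return("views disagree on embedding dimension")
    if (!all(is.finite(m))) return("embeddings must be finite")
  }
  TRUE
})

#' GOScoreMatrix: per-protein, per-term confidence scores in [0, 1]
#'
#' The common currency of every predictor in the package: a dense numeric
#' matrix with proteins as rows and GO accessions as columns, tagged with the
#' GO aspect and a flag recording whether hierarchical post-processing
#' ([postprocessScores()]) has been applied. Terms absent from the matrix are
#' interpreted as implicit zeros throughout.
#'
#' @slot scores numeric matrix, values in `[0, 1]`.
#' @slot aspect `"MF"`, `"BP"` or `"CC"`.
#' @slot postProcessed logical flag.
#' @export
setClass("GOScoreMatrix",
  representation(
    scores = "matrix",
    aspect = "character",
    postProcessed = "logical"
  ),
  prototype(postProcessed = FALSE)
)

setValidity("GOScoreMatrix", function(object) {
  s <- object@scores
  if (!is.numeric(s)) return("scores must be numeric")
  if (is.null(rownames(s)) || is.null(colnames(s))) {
    return("scores need protein rownames and GO-term colnames")
  }
  if (any(!is.finite(s)) || any(s < 0) || any(s > 1)) {
    return("scores must lie in [0, 1]")
  }
  if (length(object@aspect) != 1L || !object@aspect %in% GO_ASPECTS) {
    return("aspect must be a single value in MF/BP/CC")
  }
  TRUE
})

#' TripletFusionModel: weights of the multi-view fusion network
#'
#' Three per-view dense layers (D -> N1, shared nonlinearity), concatenation
#' to 3*N1, a fused dense layer FCLa (3*N1 -> N2) whose output is the metric
#' embedding used by the triplet loss and by guilt-by-association scoring,
#' and a sigmoid output layer FCLo (N2 -> |Q|) giving per-term confidence
#' scores. Weights are plain numeric matrices; the model is deterministic
#' given its weights.
#'
#' @slot weights list of weight matrices/bias vectors (`Wv`/`bv` per view,
#'   `Wa`/`ba`, `Wo`/`bo`).
#' @slot terms ordered candidate GO term list Q scored by the output layer.
#' @slot config list with D, N1, N2, activation, aspect, seed.
#' @export
setClass("TripletFusionModel",
  representation(weights = "list", terms = "character", config = "list")
)

setValidity("TripletFusionModel", function(object) {
  w <- object@weights
  need <- c("Wv", "bv", "Wa", "ba", "Wo", "bo")
  if (!all(need %in% names(w))) {
    return(sprintf("weights must contain %s", paste(need, collapse = ", ")))
  }
  if (length(w$Wv) != length(w$bv)) return("one bias per view layer required")
  if (ncol(w$Wo) != length(object@terms)) {
    return("output layer width must equal the candidate term count")
  }
  TRUE
})

## ---- constructors ----------------------------------------------------------

#' Construct a GOAnnotationSet
#'
#' @param annotations named list (protein ID -> character vector of GO
#'   accessions), or a two-column data.frame (protein, term).
#' @param aspect GO aspect of the annotations.
#' @param propagated whether the sets are already closed under the true-path
#'   rule.
#' @return A [GOAnnotationSet-class] object.
#' @examples
#' GOAnnotationSet(list(P1 = c("GO:0008152")), aspect = "BP")
#' @export
GOAnnotationSet <- function(annotations, aspect = c("BP", "MF", "CC"),
                            propagated = FALSE) {
  aspect <- match.arg(aspect)
  if (is.data.frame(annotations)) {
    annotations <- split(as.character(annotations[[2]]),
                         as.character(annotations[[1]]))
  }
  annotations <- lapply(annotations, function(x) sort(unique(as.character(x))))
  new("GOAnnotationSet", annotations = annotations, aspect = aspect,
      propagated = propagated)
}

#' Construct an EmbeddingBundle
#'
#' @param views list of numeric matrices (proteins x D) with protein-ID
#'   rownames; typically the mean-pooled last three layers of a protein
#'   language model.
#' @return An [EmbeddingBundle-class].
#' @export
EmbeddingBundle <- function(views) {
  views <- lapply(views, as.matrix)
  new("EmbeddingBundle", views = views)
}

#' Construct a GOScoreMatrix
#'
#' @param scores numeric matrix (proteins x terms) in `[0,1]`, or a named
#'   list of named numeric vectors (per-protein term scores) which is
#'   densified with implicit zeros.
#' @param aspect GO aspect of the scored terms.
#' @param postProcessed whether hierarchical post-processing was applied.
#' @return A [GOScoreMatrix-class].
#' @export
GOScoreMatrix <- function(scores, aspect = c("BP", "MF", "CC"),
                          postProcessed = FALSE) {
  aspect <- match.arg(aspect)
  if (is.list(scores)) {
    terms <- sort(unique(unlist(lapply(scores, names))))
    m <- matrix(0, length(scores), length(terms),
                dimnames = list(names(scores), terms))
    for (p in names(scores)) m[p, names(scores[[p]])] <- scores[[p]]
    scores <- m
  }
  new("GOScoreMatrix", scores = scores, aspect = aspect,
      postProcessed = postProcessed)
}

## ---- accessors -------------------------------------------------------------

#' @describeIn GeneOntology-class GO accessions in the DAG.
#' @param x object.
#' @param ... unused.
#' @export
setMethod("goTerms", "GeneOntology", function(x, ...) x@termIds)

#' @describeIn GeneOntology-class aspect -> root accession map.
#' @export
setMethod("goRoots", "GeneOntology", function(x) x@roots)

#' @describeIn GeneOntology-class direct parents; named list, or a single
#'   character vector when `id` is scalar.
#' @param id optional accession(s) to restrict to.
#' @export
setMethod("goParents", "GeneOntology", function(x, id = NULL, ...) {
  if (is.null(id)) return(x@parents)
  if (length(id) == 1L) x@parents[[id]] else x@parents[id]
})

#' @describeIn GeneOntology-class direct children (inverse edges).
#' @export
setMethod("goChildren", "GeneOntology", function(x, id = NULL, ...) {
  if (is.null(id)) return(x@children)
  if (length(id) == 1L) x@children[[id]] else x@children[id]
})

#' @describeIn GeneOntology-class namespace (`MF`/`BP`/`CC`) per term.
#' @export
setMethod("termNamespace", "GeneOntology", function(x, id = NULL, ...) {
  if (is.null(id)) x@namespace else x@namespace[id]
})

#' @describeIn GOAnnotationSet-class named list of per-protein term sets.
#' @param x object.
#' @param ... unused.
#' @export
setMethod("annotations", "GOAnnotationSet", function(x, ...) x@annotations)

#' @describeIn GOAnnotationSet-class GO aspect of the set.
#' @export
setMethod("goAspect", "GOAnnotationSet", function(x) x@aspect)

#' @describeIn GOAnnotationSet-class whether the true-path closure was taken.
#' @export
setMethod("isPropagated", "GOAnnotationSet", function(x) x@propagated)

#' @describeIn GOScoreMatrix-class the dense protein x term score matrix.
#' @param x object.
#' @export
setMethod("scoreMatrix", "GOScoreMatrix", function(x) x@scores)

#' @describeIn GOScoreMatrix-class GO aspect of the scores.
#' @export
setMethod("goAspect", "GOScoreMatrix", function(x) x@aspect)

#' @describeIn GOScoreMatrix-class whether hierarchical post-processing ran.
#' @export
setMethod("isPostProcessed", "GOScoreMatrix", function(x) x@postProcessed)

#' @describeIn EmbeddingBundle-class list of view matrices.
#' @param x object.
#' @export
setMethod("embeddingViews", "EmbeddingBundle", function(x) x@views)

#' @describeIn EmbeddingBundle-class protein IDs (row order of every view).
#' @export
setMethod("proteinIds", "EmbeddingBundle", function(x) rownames(x@views[[1]]))

#' @describeIn EmbeddingBundle-class embedding width D.
#' @export
setMethod("embeddingDim", "EmbeddingBundle", function(x) ncol(x@views[[1]]))

#' @export
setMethod("proteinIds", "GOAnnotationSet", function(x) names(x@annotations))

#' @export
setMethod("proteinIds", "GOScoreMatrix", function(x) rownames(x@scores))

## ---- show ------------------------------------------------------------------

setMethod("show", "GeneOntology", function(object) {
  nEdge <- sum(lengths(object@parents))
  cat(sprintf("GeneOntology with %d terms, %d parent edges\n",
              length(object@termIds), nEdge))
  tab <- table(object@namespace)
  cat("  aspects:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  cat("  roots:  ", paste(sprintf("%s:%s", names(object@roots), object@roots),
                          collapse = ", "), "\n")
})

setMethod("show", "GOAnnotationSet", function(object) {
  cat(sprintf("GOAnnotationSet (%s): %d proteins, %d distinct terms, %s\n",
              object@aspect, length(object@annotations),
              length(unique(unlist(object@annotations))),
              if (object@propagated) "propagated" else "not propagated"))
})

setMethod("show", "EmbeddingBundle", function(object) {
  cat(sprintf("EmbeddingBundle: %d proteins, %d view(s), D = %d\n",
              nrow(object@views[[1]]), length(object@views),
              ncol(object@views[[1]])))
})

setMethod("show", "GOScoreMatrix", function(object) {
  cat(sprintf("GOScoreMatrix (%s): %d proteins x %d terms, %s\n",
              object@aspect, nrow(object@scores), ncol(object@scores),
              if (object@postProcessed) "post-processed" else "raw"))
})

setMethod("show", "TripletFusionModel", function(object) {
  cfg <- object@config
  cat(sprintf(
    "TripletFusionModel: %d view(s), D = %d, N1 = %d, N2 = %d, |Q| = %d (%s)\n",
    length(object@weights$Wv), cfg$D, cfg$N1, cfg$N2, length(object@terms),
    cfg$aspect %||% "?"))
})
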