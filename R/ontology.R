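#' Topological order of the DAG (children before parents)
#'
#' @param dag a [GeneOntology-class].
#' @return character vector of accessions such that every term precedes all
#'   of its ancestors.
#' @keywords internal
.topoChildrenFirst <- function(dag) {
  g <- .ontologyGraph(dag)
  ord <- igraph::topo_sort(g, mode = "out")
  igraph::V(g)$name[as.integer(ord)]
}

#' Ancestor closure for every term of the DAG
#'
#' @param dag a [GeneOntology-class].
#' @return named list: per term, the character vector of all its ancestors
#'   (excluding the term itself).
#' @export
termAncestors <- function(dag) {
  ord <- rev(.topoChildrenFirst(dag))  # parents before children
  anc <- setNames(vector("list", length(ord)), ord)
  for (id in ord) {
    ps <- dag@parents[[id]]
    anc[[id]] <- unique(c(ps, unlist(anc[ps], use.names = FALSE)))
  }
  anc[goTerms(dag)]
}

#' Propagate annotations up the GO hierarchy (true-path rule)
#'
#' Every protein annotated with a term is, by the true-path rule, implicitly
#' annotated with all of that term's ancestors. This closes each protein's
#' term set under the parent relation. The operation is idempotent and the
#' output always contains the input.
#'
#' @param raw a [GOAnnotationSet-class].
#' @param dag the [GeneOntology-class] to propagate over.
#' @param includeRoot keep the aspect root term in the propagated sets
#'   (default `FALSE`: the root carries no information and is excluded from
#'   predictions and evaluation).
#' @param unknown what to do with accessions absent from `dag` after
#'   `alt_id` remapping: `"drop"` (with one warning) or `"error"`.
#' @return A propagated [GOAnnotationSet-class].
#' @examples
#' dag <- generateDag(syntheticConfig(nTerms = 10, seed = 1))
#' raw <- GOAnnotationSet(list(P1 = goTerms(dag)[5]), aspect = "BP")
#' propagateAnnotations(raw, dag)
#' @export
propagateAnnotations <- function(raw, dag, includeRoot = FALSE,
                                 unknown = c("drop", "error")) {
  unknown <- match.arg(unknown)
  .assertFlag(includeRoot, "includeRoot")
  stopifnot(is(raw, "GOAnnotationSet"), is(dag, "GeneOntology"))
  anc <- termAncestors(dag)
  known <- goTerms(dag)
  root <- goRoots(dag)[[goAspect(raw)]]
  nUnknown <- 0L
  out <- lapply(annotations(raw), function(terms) {
    hit <- terms %in% names(dag@altIds)
    terms[hit] <- dag@altIds[terms[hit]]
    bad <- setdiff(terms, known)
    if (length(bad)) {
      if (unknown == "error") {
        stop("unknown GO accession(s): ", paste(head(bad, 5), collapse = ", "),
             call. = FALSE)
      }
      nUnknown <<- nUnknown + length(bad)
      terms <- setdiff(terms, bad)
    }
    full <- unique(c(terms, unlist(anc[terms], use.names = FALSE)))
    if (!includeRoot && !is.null(root)) full <- setdiff(full, root)
    sort(full)
  })
  if (nUnknown > 0L) {
    warning(sprintf("dropped %d annotation(s) with accessions not in the DAG",
                    nUnknown), call. = FALSE)
  }
  GOAnnotationSet(out, aspect = goAspect(raw), propagated = TRUE)
}

#' Hierarchically post-process prediction scores
#'
#' Enforces consistency of confidence scores with the GO hierarchy: the
#' post-processed score of a term is the maximum of its own score and the
#' post-processed scores of all its direct children, computed bottom-up
#' (children before parents) so a single pass reaches the fixpoint. After
#' application, every parent scores at least as high as each of its children,
#' and no score decreases. Terms absent from the input matrix are treated as
#' implicit zeros, so an unscored ancestor can still be lifted by a scored
#' descendant; such ancestors (except the aspect root) are added to the
#' output.
#'
#' @param scores a [GOScoreMatrix-class].
#' @param dag the [GeneOntology-class] giving the hierarchy.
#' @return A [GOScoreMatrix-class] with `isPostProcessed(x) == TRUE`.
#' @export
postprocessScores <- function(scores, dag) {
  stopifnot(is(scores, "GOScoreMatrix"), is(dag, "GeneOntology"))
  m <- scoreMatrix(scores)
  if (any(m < 0 | m > 1)) stop("scores must lie in [0, 1]", call. = FALSE)
  known <- intersect(colnames(m), goTerms(dag))
  if (length(known) < ncol(m)) {
    warning(sprintf("dropping %d scored term(s) not in the DAG",
                    ncol(m) - length(known)), call. = FALSE)
    m <- m[, known, drop = FALSE]
  }
  anc <- termAncestors(dag)
  root <- goRoots(dag)[[goAspect(scores)]]
  cols <- setdiff(
    unique(c(colnames(m), unlist(anc[colnames(m)], use.names = FALSE))),
    root)
  full <- matrix(0, nrow(m), length(cols),
                 dimnames = list(rownames(m), cols))
  full[, colnames(m)] <- m
  for (q in .topoChildrenFirst(dag)) {
    if (!(q %in% cols)) next
    for (p in dag@parents[[q]]) {
      if (p %in% cols) full[, p] <- pmax(full[, p], full[, q])
    }
  }
  GOScoreMatrix(full, aspect = goAspect(scores), postProcessed = TRUE)
}

#' Information content of GO terms from a training annotation set
#'
#' `IC(q) = -log_base(n_q / N)` with `n_q` the number of training proteins
#' annotated (after propagation) with term `q` and `N` the number of
#' training proteins. Terms never seen in training receive a ceiling IC,
#' by default `-log_base(1 / (N + 1))`, i.e. just above the IC of a
#' singleton term.
#'
#' @param train a propagated [GOAnnotationSet-class].
#' @param base logarithm base (default 2, IC in bits).
#' @param ceiling IC assigned to unseen terms; default `-log_base(1/(N+1))`.
#' @return Named numeric vector of ICs over the terms seen in training, with
#'   attributes `ceiling` and `nProteins`.
#' @examples
#' a <- GOAnnotationSet(list(P1 = "GO:0000002", P2 = "GO:0000002"),
#'                      aspect = "BP", propagated = TRUE)
#' informationContent(a)  # term in all proteins: IC = 0
#' @export
informationContent <- function(train, base = 2, ceiling = NULL) {
  stopifnot(is(train, "GOAnnotationSet"))
  if (!isPropagated(train)) {
    stop("information content requires a propagated annotation set",
         call. = FALSE)
  }
  a <- annotations(train)
  if (!length(a)) stop("empty training annotation set", call. = FALSE)
  N <- length(a)
  counts <- table(unlist(a, use.names = FALSE))
  ic <- -log(as.numeric(counts) / N, base = base)
  names(ic) <- names(counts)
  if (is.null(ceiling)) ceiling <- -log(1 / (N + 1), base = base)
  attr(ic, "ceiling") <- ceiling
  attr(ic, "nProteins") <- N
  ic
}

# IC lookup with ceiling fallback for unseen terms
.icLookup <- function(ic, terms, warnMissing = TRUE) {
  out <- ic[terms]
  miss <- is.na(out)
  if (any(miss)) {
    if (warnMissing) {
      warning(sprintf("%d term(s) without training IC: using ceiling IC",
                      sum(miss)), call. = FALSE)
    }
    out[miss] <- attr(ic, "ceiling") %||% max(ic)
  }
  names(out) <- terms
  unname(out)
}
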