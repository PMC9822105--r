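#' @export
setGeneric("goTerms", function(x, ...) standardGeneric("goTerms"))

#' @export
setGeneric("goRoots", function(x) standardGeneric("goRoots"))

#' @export
setGeneric("goParents", function(x, ...) standardGeneric("goParents"))

#' @export
setGeneric("goChildren", function(x, ...) standardGeneric("goChildren"))

#' @export
setGeneric("termNamespace", function(x, ...) standardGeneric("termNamespace"))

#' @export
setGeneric("annotations", function(x, ...) standardGeneric("annotations"))

#' @export
setGeneric("goAspect", function(x) standardGeneric("goAspect"))

#' @export
setGeneric("isPropagated", function(x) standardGeneric("isPropagated"))

#' @export
setGeneric("scoreMatrix", function(x) standardGeneric("scoreMatrix"))

#' @export
setGeneric("isPostProcessed", function(x) standardGeneric("isPostProcessed"))

#' @export
setGeneric("embeddingViews", function(x) standardGeneric("embeddingViews"))

#' @export
setGeneric("proteinIds", function(x) standardGeneric("proteinIds"))

#' @export
setGeneric("embeddingDim", function(x) standardGeneric("embeddingDim"))
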