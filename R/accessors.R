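#' Accessors for package classes
#'
#' Small accessor generics so callers never reach into slots directly.
#'
#' @param x an object of one of the package's S4 classes.
#' @return `reportId`: the report identifier; `lemmas`: the ordered content
#'   lemmas; `graphNodes`/`graphEdges`: node vector and ordered edge matrix
#'   of a [SpeechGraph-class]; `networkNodes`/`networkEdges`/
#'   `wordCentrality`: the node table, edge table and centrality vector of
#'   a [CooccurrenceNetwork-class]; `conditionSlopes`: the per-condition
#'   slope table of an [AssociationResult-class]; `pairwiseTable`: the
#'   contrast table of a [ComparisonResult-class].
#' @name accessors
#' @aliases reportId lemmas graphNodes graphEdges networkNodes networkEdges
#'   wordCentrality conditionSlopes pairwiseTable
NULL

#' @rdname accessors
#' @export
setGeneric("reportId", function(x) standardGeneric("reportId"))
#' @rdname accessors
#' @export
setGeneric("lemmas", function(x) standardGeneric("lemmas"))
#' @rdname accessors
#' @export
setGeneric("graphNodes", function(x) standardGeneric("graphNodes"))
#' @rdname accessors
#' @export
setGeneric("graphEdges", function(x) standardGeneric("graphEdges"))
#' @rdname accessors
#' @export
setGeneric("networkNodes", function(x) standardGeneric("networkNodes"))
#' @rdname accessors
#' @export
setGeneric("networkEdges", function(x) standardGeneric("networkEdges"))
#' @rdname accessors
#' @export
setGeneric("wordCentrality", function(x) standardGeneric("wordCentrality"))
#' @rdname accessors
#' @export
setGeneric("conditionSlopes", function(x) standardGeneric("conditionSlopes"))
#' @rdname accessors
#' @export
setGeneric("pairwiseTable", function(x) standardGeneric("pairwiseTable"))

#' @rdname accessors
setMethod("reportId", "LemmaSequence", function(x) x@reportId)
#' @rdname accessors
setMethod("reportId", "SpeechGraph", function(x) x@reportId)
#' @rdname accessors
setMethod("lemmas", "LemmaSequence", function(x) x@lemmas)
#' @rdname accessors
setMethod("graphNodes", "SpeechGraph", function(x) x@nodes)
#' @rdname accessors
setMethod("graphEdges", "SpeechGraph", function(x) x@edges)
#' @rdname accessors
setMethod("networkNodes", "CooccurrenceNetwork", function(x) x@nodes)
#' @rdname accessors
setMethod("networkEdges", "CooccurrenceNetwork", function(x) x@edges)
#' @rdname accessors
setMethod("wordCentrality", "CooccurrenceNetwork", function(x) x@centrality)
#' @rdname accessors
setMethod("conditionSlopes", "AssociationResult", function(x) x@slopes)
#' @rdname accessors
setMethod("pairwiseTable", "ComparisonResult", function(x) x@contrasts)
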