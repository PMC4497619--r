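#' @include AllClasses.R
NULL

#' Accessors for hetnet objects
#'
#' `metaNodes()` and `metaEdges()` return the schema tables; `metaGraph()`
#' the schema of a network; `nodes()` and `edges()` the node and edge tables
#' of a [HetNet-class].
#'
#' @param x a [MetaGraph-class] or [HetNet-class].
#' @return a data.frame (or, for `metaGraph()`, a [MetaGraph-class]).
#' @name accessors
#' @aliases metaNodes metaEdges metaGraph nodes edges
#' @export
setGeneric("metaNodes", function(x) standardGeneric("metaNodes"))

#' @rdname accessors
#' @export
setGeneric("metaEdges", function(x) standardGeneric("metaEdges"))

#' @rdname accessors
#' @export
setGeneric("metaGraph", function(x) standardGeneric("metaGraph"))

#' @rdname accessors
#' @export
setGeneric("nodes", function(x) standardGeneric("nodes"))

#' @rdname accessors
#' @export
setGeneric("edges", function(x) standardGeneric("edges"))
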