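#' MetaGraph: the schema of a heterogeneous network
#'
#' A metagraph declares the node types (metanodes) and edge types (metaedges)
#' that a heterogeneous network may contain. Metanodes carry a short unique
#' abbreviation (used to name metapaths, e.g. `G` for Gene); metaedges carry a
#' source metanode, target metanode, relationship kind, direction, and a
#' lowercase kind abbreviation (e.g. `a` for association). Each metaedge gets
#' a compact identifier of the form `<srcAbbrev><kindAbbrev><tgtAbbrev>`,
#' e.g. `DaG` for Disease-association-Gene.
#'
#' @slot metanodes data.frame with columns `identifier`, `abbreviation`.
#' @slot metaedges data.frame with columns `source`, `target`, `kind`,
#'   `direction`, `abbreviation`, and the derived `id`.
#'
#' @seealso [buildMetaGraph()], [readMetaGraph()], [bundledMetaGraph()]
#' @export
setClass("MetaGraph",
  representation(metanodes = "data.frame", metaedges = "data.frame"))

validMetaGraph <- function(object) {
  mn <- object@metanodes
  me <- object@metaedges
  msgs <- character()
  need <- c("identifier", "abbreviation")
  if (!all(need %in% names(mn)))
    return("metanodes must have columns identifier, abbreviation")
  needE <- c("source", "target", "kind", "direction", "abbreviation", "id")
  if (nrow(me) > 0 && !all(needE %in% names(me)))
    return("metaedges must have columns source, target, kind, direction, abbreviation, id")
  if (anyDuplicated(mn$identifier))
    msgs <- c(msgs, sprintf("duplicate metanode identifier: %s",
                            paste(unique(mn$identifier[duplicated(mn$identifier)]), collapse = ", ")))
  if (anyDuplicated(mn$abbreviation))
    msgs <- c(msgs, sprintf("duplicate metanode abbreviation: %s",
                            paste(unique(mn$abbreviation[duplicated(mn$abbreviation)]), collapse = ", ")))
  if (any(!grepl("^[A-Z][a-z0-9]*$", mn$abbreviation)))
    msgs <- c(msgs, "metanode abbreviations must start uppercase followed by lowercase/digits")
  if (nrow(me) > 0) {
    missing <- setdiff(c(me$source, me$target), mn$identifier)
    if (length(missing))
      msgs <- c(msgs, sprintf("metaedge endpoint not a declared metanode: %s",
                              paste(missing, collapse = ", ")))
    trip <- paste(me$source, me$target, me$kind)
    if (anyDuplicated(trip))
      msgs <- c(msgs, sprintf("duplicate (source, target, kind) metaedge: %s",
                              paste(unique(trip[duplicated(trip)]), collapse = "; ")))
    if (any(!me$direction %in% c("directed", "undirected")))
      msgs <- c(msgs, "metaedge direction must be 'directed' or 'undirected'")
    if (any(!grepl("^[a-z0-9]+$", me$abbreviation)))
      msgs <- c(msgs, "metaedge (kind) abbreviations must be lowercase")
    # abbreviation must be unique among metaedges sharing an endpoint pair,
    # otherwise metapath abbreviations would be ambiguous
    pairKey <- ifelse(me$source <= me$target,
                      paste(me$source, me$target), paste(me$target, me$source))
    ab <- paste(pairKey, me$abbreviation)
    if (anyDuplicated(ab))
      msgs <- c(msgs, "metaedge abbreviation reused between the same endpoint pair")
    if (anyDuplicated(me$id))
      msgs <- c(msgs, "metaedge ids are not unique; adjust abbreviations")
  }
  if (length(msgs)) msgs else TRUE
}
setValidity("MetaGraph", validMetaGraph)

#' HetNet: a typed heterogeneous network instance
#'
#' Nodes and edges are each annotated with their meta-type. Undirected edges
#' are stored in one canonical orientation; the per-metaedge adjacency index
#' supports metaedge-specific neighbor and degree queries.
#'
#' @slot metagraph the [MetaGraph-class] schema.
#' @slot nodes data.frame with columns `identifier`, `metanode`, `name`.
#' @slot edges data.frame with columns `source`, `metaedge` (metaedge id),
#'   `target`, `weight` (numeric, `NA` for unweighted).
#' @slot adjacency per-metaedge adjacency index (list of per-node neighbor
#'   character vectors), built at construction; treat as internal.
#'
#' @seealso [hetNet()], [loadHetNet()], [writeHetNet()]
#' @export
setClass("HetNet",
  representation(metagraph = "MetaGraph", nodes = "data.frame",
                 edges = "data.frame", adjacency = "list"))

validHetNet <- function(object) {
  nd <- object@nodes
  eg <- object@edges
  mg <- object@metagraph
  msgs <- character()
  if (!all(c("identifier", "metanode", "name") %in% names(nd)))
    return("nodes must have columns identifier, metanode, name")
  if (nrow(eg) > 0 && !all(c("source", "metaedge", "target", "weight") %in% names(eg)))
    return("edges must have columns source, metaedge, target, weight")
  if (any(!nd$metanode %in% mg@metanodes$identifier))
    msgs <- c(msgs, "node with undeclared metanode")
  if (anyDuplicated(paste(nd$identifier, nd$metanode)))
    msgs <- c(msgs, "duplicate (identifier, metanode) node")
  if (anyDuplicated(nd$identifier))
    msgs <- c(msgs, "node identifiers must be globally unique")
  if (nrow(eg) > 0) {
    meRow <- match(eg$metaedge, mg@metaedges$id)
    if (anyNA(meRow)) {
      msgs <- c(msgs, "edge with undeclared metaedge id")
    } else {
      ndType <- stats::setNames(nd$metanode, nd$identifier)
      sType <- ndType[eg$source]
      tType <- ndType[eg$target]
      if (anyNA(sType) || anyNA(tType)) {
        msgs <- c(msgs, "edge endpoint missing from node table")
      } else {
        declS <- mg@metaedges$source[meRow]
        declT <- mg@metaedges$target[meRow]
        bad <- sType != declS | tType != declT
        if (any(bad))
          msgs <- c(msgs, sprintf("%d edge(s) whose endpoint metanodes contradict their metaedge", sum(bad)))
        sameType <- declS == declT
        uncanon <- sameType & eg$source > eg$target
        if (any(uncanon))
          msgs <- c(msgs, "same-type undirected edges must be stored with source <= target")
      }
      if (any(eg$source == eg$target))
        msgs <- c(msgs, "self-edges are not allowed")
      if (anyDuplicated(paste(eg$source, eg$metaedge, eg$target)))
        msgs <- c(msgs, "duplicate (source, metaedge, target) edges")
    }
  }
  if (length(msgs)) msgs else TRUE
}
setValidity("HetNet", validHetNet)

#' MetaPath: an ordered metaedge sequence between two metanodes
#'
#' A metapath is the type of a path: consecutive metaedges chain so that the
#' target metanode of one step is the source metanode of the next. Metapaths
#' may revisit metanodes and metaedges (e.g. `GaDaGaD`); only concrete paths
#' are forbidden from repeating nodes.
#'
#' @slot metanodeIds metanode identifiers along the path (length + 1 entries).
#' @slot metanodeAbbrevs their abbreviations.
#' @slot metaedgeIds metaedge ids of each step.
#' @slot kindAbbrevs kind abbreviation of each step.
#'
#' @seealso [enumerateMetaPaths()], [metaPathAbbrev()], [parseMetaPath()]
#' @export
setClass("MetaPath",
  representation(metanodeIds = "character", metanodeAbbrevs = "character",
                 metaedgeIds = "character", kindAbbrevs = "character"))

setValidity("MetaPath", function(object) {
  L <- length(object@metaedgeIds)
  if (L < 1) return("a metapath has at least one metaedge")
  if (length(object@metanodeIds) != L + 1)
    return("metanodeIds must have one more entry than metaedgeIds")
  if (length(object@metanodeAbbrevs) != L + 1 || length(object@kindAbbrevs) != L)
    return("abbreviation slots out of step with path length")
  TRUE
})

#' ModelFit: a regularized logistic regression fit
#'
#' Stores the elastic-net mixing parameter, the cross-validation-selected
#' penalty, the intercept and standardized coefficients (the model is fit on
#' z-scored features), the standardization transform needed to score new raw
#' feature rows, and the cross-validated deviance profile over the lambda
#' grid.
#'
#' @slot alpha elastic-net mixing parameter in `[0, 1]` (0 ridge, 1 lasso).
#' @slot lambda selected regularization strength (one-standard-error rule).
#' @slot intercept model intercept on the standardized scale.
#' @slot coefficients named standardized coefficients, one per feature.
#' @slot center,scale column means / SDs of the standardization transform.
#' @slot cvProfile data.frame of `lambda`, `meanDeviance`, `sdDeviance`.
#'
#' @seealso [fitRegularizedLogistic()], [predictProbabilities()]
#' @export
setClass("ModelFit",
  representation(alpha = "numeric", lambda = "numeric", intercept = "numeric",
                 coefficients = "numeric", center = "numeric",
                 scale = "numeric", cvProfile = "data.frame"))

setValidity("ModelFit", function(object) {
  msgs <- character()
  if (object@alpha < 0 || object@alpha > 1)
    msgs <- c(msgs, "alpha must lie in [0, 1]")
  if (object@lambda <= 0) msgs <- c(msgs, "lambda must be positive")
  if (!all(is.finite(object@coefficients)))
    msgs <- c(msgs, "coefficients must be finite")
  if (length(object@coefficients) != length(object@center) ||
      length(object@coefficients) != length(object@scale))
    msgs <- c(msgs, "coefficients, center and scale must align")
  if (length(msgs)) msgs else TRUE
})
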