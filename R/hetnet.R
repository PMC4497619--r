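#' @include metagraph.R
NULL

# Resolve the metaedge id for each raw edge row and canonicalize orientation.
# Raw rows may name the metaedge by id ("DaG"), by kind ("association"), or by
# kind abbreviation ("a"); kind-based resolution uses the endpoint node types.
# Returns a canonical data.frame(source, metaedge, target, weight) or raises
# an error naming the offending row.
canonicalizeEdges <- function(metagraph, nodes, edges) {
  me <- metagraph@metaedges
  ndType <- stats::setNames(nodes$metanode, nodes$identifier)
  n <- nrow(edges)
  if (n == 0)
    return(data.frame(source = character(0), metaedge = character(0),
                      target = character(0), weight = numeric(0),
                      stringsAsFactors = FALSE))
  src <- as.character(edges$source)
  tgt <- as.character(edges$target)
  lab <- as.character(edges$metaedge)
  wt <- if ("weight" %in% names(edges)) suppressWarnings(as.numeric(edges$weight)) else rep(NA_real_, n)
  outS <- character(n); outT <- character(n); outM <- character(n)
  sTypeAll <- unname(ndType[src])
  tTypeAll <- unname(ndType[tgt])
  for (i in seq_len(n)) {
    sT <- sTypeAll[i]
    tT <- tTypeAll[i]
    if (is.na(sT) || is.na(tT))
      stopf("edge row %d references a missing node: %s",
            i, if (is.na(sT)) src[i] else tgt[i])
    hit <- which(me$id == lab[i])
    if (length(hit) == 0)
      hit <- which((me$kind == lab[i] | me$abbreviation == lab[i]) &
                   ((me$source == sT & me$target == tT) |
                    (me$source == tT & me$target == sT)))
    if (length(hit) == 0)
      stopf("edge row %d: no metaedge '%s' joining types %s and %s",
            i, lab[i], sT, tT)
    if (length(hit) > 1)
      stopf("edge row %d: metaedge label '%s' is ambiguous for types %s and %s",
            i, lab[i], sT, tT)
    decl <- me[hit, ]
    if (decl$source == decl$target) {
      if (sT != decl$source || tT != decl$target)
        stopf("edge row %d: endpoint types (%s, %s) contradict metaedge %s",
              i, sT, tT, decl$id)
      # same-type: lexicographic canonical orientation
      if (src[i] > tgt[i]) { tmp <- src[i]; src[i] <- tgt[i]; tgt[i] <- tmp }
    } else if (sT == decl$source && tT == decl$target) {
      # already oriented source-type first
    } else if (sT == decl$target && tT == decl$source) {
      if (decl$direction == "directed")
        stopf("edge row %d: directed metaedge %s given in reverse orientation",
              i, decl$id)
      tmp <- src[i]; src[i] <- tgt[i]; tgt[i] <- tmp
    } else {
      stopf("edge row %d: endpoint types (%s, %s) contradict metaedge %s",
            i, sT, tT, decl$id)
    }
    if (src[i] == tgt[i])
      stopf("edge row %d: self-edge on node %s", i, src[i])
    outS[i] <- src[i]; outT[i] <- tgt[i]; outM[i] <- decl$id
  }
  data.frame(source = outS, metaedge = outM, target = outT, weight = wt,
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

buildAdjacency <- function(metagraph, nodes, edges) {
  adj <- list()
  for (id in metagraph@metaedges$id) {
    sub <- edges[edges$metaedge == id, , drop = FALSE]
    ends <- c(sub$source, sub$target)
    nbrs <- c(sub$target, sub$source)
    adj[[id]] <- split(nbrs, factor(ends, levels = unique(ends)))
  }
  adj
}

#' Construct a heterogeneous network
#'
#' Builds a validated [HetNet-class] from node and edge tables. Edge rows are
#' canonicalized (undirected same-type edges stored with the lexicographically
#' smaller node first; typed edges oriented source-metanode first) and exact
#' duplicates are collapsed with a warning reporting the count, since merged
#' primary resources commonly repeat records.
#'
#' @param metagraph the [MetaGraph-class] schema.
#' @param nodes data.frame with columns `identifier`, `metanode`, and
#'   optionally `name` (defaults to the identifier).
#' @param edges data.frame with columns `source`, `metaedge` (metaedge id,
#'   kind, or kind abbreviation), `target`, and optionally `weight`.
#' @return a [HetNet-class].
#' @export
hetNet <- function(metagraph, nodes, edges = NULL) {
  if (is.null(nodes$name)) nodes$name <- nodes$identifier
  nodes <- data.frame(identifier = as.character(nodes$identifier),
                      metanode = as.character(nodes$metanode),
                      name = as.character(nodes$name),
                      stringsAsFactors = FALSE)
  if (is.null(edges))
    edges <- data.frame(source = character(0), metaedge = character(0),
                        target = character(0))
  canon <- canonicalizeEdges(metagraph, nodes, edges)
  key <- paste(canon$source, canon$metaedge, canon$target)
  dup <- duplicated(key)
  if (any(dup)) {
    warnf("collapsed %d duplicate edge record(s)", sum(dup))
    canon <- canon[!dup, , drop = FALSE]
  }
  rownames(canon) <- NULL
  net <- new("HetNet", metagraph = metagraph, nodes = nodes, edges = canon,
             adjacency = buildAdjacency(metagraph, nodes, canon))
  validObject(net)
  net
}

#' Read and write hetnet node/edge tables
#'
#' Tables are tab-separated UTF-8 with a header row. The node table has
#' columns `identifier`, `metanode`, `name`; the edge table is SIF-compatible
#' with columns `source`, `metaedge`, `target` and an optional `weight`
#' column. `loadHetNet(writeHetNet(net, ...))` reproduces the network up to
#' row ordering.
#'
#' @param nodeFile,edgeFile file paths.
#' @param metagraph the [MetaGraph-class] schema the tables must conform to.
#' @return `loadHetNet()` a [HetNet-class]; `writeHetNet()` the paths,
#'   invisibly.
#' @export
loadHetNet <- function(nodeFile, edgeFile, metagraph) {
  nodes <- readTsv(nodeFile)
  if (!all(c("identifier", "metanode") %in% names(nodes)))
    stopf("node table needs columns 'identifier' and 'metanode'")
  edges <- readTsv(edgeFile)
  if (!all(c("source", "metaedge", "target") %in% names(edges)))
    stopf("edge table needs columns 'source', 'metaedge' and 'target'")
  hetNet(metagraph, nodes, edges)
}

#' @rdname loadHetNet
#' @param hetnet a [HetNet-class].
#' @export
writeHetNet <- function(hetnet, nodeFile, edgeFile) {
  writeTsv(hetnet@nodes, nodeFile)
  eg <- hetnet@edges
  if (all(is.na(eg$weight))) eg$weight <- NULL
  writeTsv(eg, edgeFile)
  invisible(c(nodes = nodeFile, edges = edgeFile))
}

#' @rdname accessors
#' @export
setMethod("metaGraph", "HetNet", function(x) x@metagraph)

#' @rdname accessors
#' @export
setMethod("nodes", "HetNet", function(x) x@nodes)

#' @rdname accessors
#' @export
setMethod("edges", "HetNet", function(x) x@edges)

setMethod("show", "HetNet", function(object) {
  cat(sprintf("HetNet with %d nodes and %d edges\n",
              nrow(object@nodes), nrow(object@edges)))
  tab <- table(factor(object@edges$metaedge,
                      levels = object@metagraph@metaedges$id))
  for (id in names(tab))
    cat(sprintf("  %-12s %d\n", id, tab[[id]]))
})

#' Canonical edge key
#'
#' Returns the canonical identity string of an edge given in either
#' orientation, suitable for use in masked-edge sets.
#'
#' @param hetnet a [HetNet-class].
#' @param u,v endpoint node identifiers.
#' @param metaedge metaedge id.
#' @return a character key; the edge need not exist in the network.
#' @export
edgeKey <- function(hetnet, u, v, metaedge) {
  me <- hetnet@metagraph@metaedges
  row <- me[me$id == metaedge, ]
  if (nrow(row) != 1) stopf("unknown metaedge: %s", metaedge)
  ndType <- hetnet@nodes$metanode[match(c(u, v), hetnet@nodes$identifier)]
  if (anyNA(ndType)) stopf("unknown node in edgeKey: %s",
                           paste(c(u, v)[is.na(ndType)], collapse = ", "))
  if (row$source == row$target) {
    if (u > v) { tmp <- u; u <- v; v <- tmp }
  } else if (ndType[1] == row$target) {
    tmp <- u; u <- v; v <- tmp
  }
  edgeKeyString(u, metaedge, v)
}

# Neighbors of `node` under `metaedge`, honoring a masked-edge key set.
hnNeighbors <- function(hetnet, node, metaedge, masked = character()) {
  nb <- hetnet@adjacency[[metaedge]][[node]]
  if (is.null(nb)) return(character(0))
  if (length(masked)) {
    keys <- vapply(nb, function(v) edgeKey(hetnet, node, v, metaedge), "")
    nb <- nb[!keys %in% masked]
  }
  nb
}

#' Metaedge-specific node degree
#'
#' The number of edges of exactly the given metaedge incident to a node;
#' edges of other metaedges are ignored. Edges whose canonical keys appear in
#' `masked` are treated as absent.
#'
#' @param hetnet a [HetNet-class].
#' @param node node identifier.
#' @param metaedge metaedge id.
#' @param masked character vector of canonical edge keys (see [edgeKey()])
#'   treated as removed.
#' @return a non-negative integer.
#' @export
nodeDegree <- function(hetnet, node, metaedge, masked = character()) {
  if (!node %in% hetnet@nodes$identifier) stopf("unknown node: %s", node)
  if (!metaedge %in% hetnet@metagraph@metaedges$id)
    stopf("unknown metaedge: %s", metaedge)
  length(hnNeighbors(hetnet, node, metaedge, masked))
}

#' Filter weighted edge records by an inclusion threshold
#'
#' Retains records whose weight meets or exceeds the threshold (inclusive,
#' matching the convention that thresholds state the minimum value required
#' for inclusion) and drops the weight column, yielding unweighted edges.
#'
#' @param edgeRecords data.frame with columns `source`, `metaedge`, `target`,
#'   `weight`.
#' @param metaedge metaedge id/kind the threshold applies to; records of
#'   other metaedges pass through unchanged.
#' @param threshold numeric inclusion threshold.
#' @return the filtered edge data.frame without a weight column.
#' @export
filterEdgesByWeight <- function(edgeRecords, metaedge, threshold) {
  sel <- edgeRecords$metaedge == metaedge
  w <- suppressWarnings(as.numeric(edgeRecords$weight))
  if (any(sel & is.na(w)))
    stopf("record(s) missing a numeric weight at row(s): %s",
          paste(which(sel & is.na(w)), collapse = ", "))
  keep <- !sel | w >= threshold
  out <- edgeRecords[keep, setdiff(names(edgeRecords), "weight"), drop = FALSE]
  rownames(out) <- NULL
  out
}

# Rebuild a network with the given canonical edge keys removed.
removeEdges <- function(hetnet, keys) {
  eg <- hetnet@edges
  eKeys <- edgeKeyString(eg$source, eg$metaedge, eg$target)
  eg <- eg[!eKeys %in% keys, , drop = FALSE]
  rownames(eg) <- NULL
  new("HetNet", metagraph = hetnet@metagraph, nodes = hetnet@nodes,
      edges = eg, adjacency = buildAdjacency(hetnet@metagraph, hetnet@nodes, eg))
}
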