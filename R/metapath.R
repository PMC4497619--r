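#' @include hetnet.R
NULL

# Build a MetaPath from a start metanode and a chaining metaedge-id sequence.
metaPathFromIds <- function(metagraph, startMetanode, metaedgeIds) {
  me <- metagraph@metaedges
  nodesSeq <- startMetanode
  kinds <- character(length(metaedgeIds))
  cur <- startMetanode
  for (i in seq_along(metaedgeIds)) {
    row <- me[me$id == metaedgeIds[i], ]
    if (nrow(row) != 1) stopf("unknown metaedge id: %s", metaedgeIds[i])
    if (row$source == cur) {
      cur <- row$target
    } else if (row$target == cur && row$direction == "undirected") {
      cur <- row$source
    } else {
      stopf("metaedge %s does not chain from metanode %s", row$id, cur)
    }
    nodesSeq <- c(nodesSeq, cur)
    kinds[i] <- row$abbreviation
  }
  new("MetaPath", metanodeIds = nodesSeq,
      metanodeAbbrevs = metanodeAbbrev(metagraph, nodesSeq),
      metaedgeIds = metaedgeIds, kindAbbrevs = kinds)
}

#' Length of a metapath
#' @param x a [MetaPath-class].
#' @return number of metaedges.
#' @export
setMethod("length", "MetaPath", function(x) length(x@metaedgeIds))

#' Metapath abbreviation
#'
#' Renders a metapath as alternating metanode abbreviations (uppercase) and
#' metaedge kind abbreviations (lowercase), e.g.
#' Gene-expression-Tissue-localization-Disease becomes `"GeTlD"`.
#' Abbreviations are injective over the metapaths of a metagraph, and
#' [parseMetaPath()] inverts them.
#'
#' @param metapath a [MetaPath-class].
#' @return a character scalar.
#' @export
metaPathAbbrev <- function(metapath) {
  L <- length(metapath@metaedgeIds)
  out <- character(2 * L + 1)
  out[seq(1, 2 * L + 1, by = 2)] <- metapath@metanodeAbbrevs
  out[seq(2, 2 * L, by = 2)] <- metapath@kindAbbrevs
  paste(out, collapse = "")
}

#' Parse a metapath abbreviation
#'
#' Inverts [metaPathAbbrev()] relative to a metagraph, using backtracking
#' over metanode abbreviations (which may span several characters).
#'
#' @param metagraph a [MetaGraph-class].
#' @param abbrev abbreviation string, e.g. `"GiGaD"`.
#' @return a [MetaPath-class]; error if the string does not parse uniquely.
#' @export
parseMetaPath <- function(metagraph, abbrev) {
  mn <- metagraph@metanodes
  me <- metagraph@metaedges
  solutions <- list()
  descend <- function(rest, curMetanode, ids) {
    if (!nzchar(rest)) {
      if (length(ids)) solutions[[length(solutions) + 1]] <<- ids
      return(invisible(NULL))
    }
    # consume one kind abbreviation + one metanode abbreviation
    for (j in seq_len(nrow(me))) {
      fromS <- me$source[j] == curMetanode
      fromT <- me$target[j] == curMetanode && me$direction[j] == "undirected"
      if (!fromS && !fromT) next
      nexts <- unique(c(if (fromS) me$target[j], if (fromT) me$source[j]))
      for (nxt in nexts) {
        token <- paste0(me$abbreviation[j], metanodeAbbrev(metagraph, nxt))
        if (startsWith(rest, token))
          descend(substring(rest, nchar(token) + 1), nxt, c(ids, me$id[j]))
      }
    }
  }
  starts <- mn$identifier[vapply(mn$abbreviation,
                                 function(a) startsWith(abbrev, a), TRUE)]
  for (s in starts)
    descend(substring(abbrev, nchar(metanodeAbbrev(metagraph, s)) + 1), s,
            character(0))
  if (length(solutions) == 0) stopf("cannot parse metapath '%s'", abbrev)
  uniq <- unique(vapply(solutions, paste, "", collapse = " "))
  if (length(uniq) > 1) stopf("metapath abbreviation '%s' is ambiguous", abbrev)
  # recover the start metanode from the first solution
  ids <- solutions[[1]]
  first <- me[me$id == ids[1], ]
  cand <- unique(c(first$source, first$target))
  start <- cand[vapply(cand, function(x)
    startsWith(abbrev, metanodeAbbrev(metagraph, x)), TRUE)]
  for (s in start) {
    mp <- tryCatch(metaPathFromIds(metagraph, s, ids), error = function(e) NULL)
    if (!is.null(mp) && metaPathAbbrev(mp) == abbrev) return(mp)
  }
  stopf("cannot parse metapath '%s'", abbrev)
}

#' Enumerate metapaths between two metanodes
#'
#' Every chaining metaedge sequence of length 1 to `maxLength` from the
#' source to the target metanode, in deterministic order (by length, then
#' abbreviation). Walks on the metagraph may revisit metanodes and metaedges
#' (`GaDaGaD` and `GiGiGaD` are legal); only concrete paths are later
#' restricted to distinct nodes.
#'
#' @param metagraph a [MetaGraph-class].
#' @param sourceMetanode,targetMetanode metanode identifiers.
#' @param maxLength maximum number of metaedges (default 3).
#' @return a list of [MetaPath-class] objects.
#' @examples
#' mg <- bundledMetaGraph()
#' mps <- enumerateMetaPaths(mg, "Gene", "Disease", 3)
#' length(mps)  # 23, including the bare association metapath GaD
#' @export
enumerateMetaPaths <- function(metagraph, sourceMetanode, targetMetanode,
                               maxLength = 3) {
  if (maxLength < 1) stopf("maxLength must be at least 1")
  mn <- metagraph@metanodes$identifier
  if (!sourceMetanode %in% mn) stopf("unknown metanode: %s", sourceMetanode)
  if (!targetMetanode %in% mn) stopf("unknown metanode: %s", targetMetanode)
  found <- list()
  walk <- function(cur, ids) {
    if (length(ids) > 0 && cur == targetMetanode)
      found[[length(found) + 1]] <<- ids
    if (length(ids) == maxLength) return(invisible(NULL))
    inc <- incidentMetaEdges(metagraph, cur)
    for (j in seq_len(nrow(inc)))
      walk(inc$next_metanode[j], c(ids, inc$id[j]))
  }
  walk(sourceMetanode, character(0))
  paths <- lapply(found, function(ids)
    metaPathFromIds(metagraph, sourceMetanode, ids))
  abbrevs <- vapply(paths, metaPathAbbrev, "")
  lens <- vapply(paths, length, 1L)
  paths[order(lens, abbrevs)]
}

setMethod("show", "MetaPath", function(object) {
  cat(sprintf("MetaPath %s (%s, length %d)\n", metaPathAbbrev(object),
              paste(object@metanodeIds, collapse = "-"),
              length(object@metaedgeIds)))
})

#' Extract concrete paths instantiating a metapath
#'
#' Constrained depth-first traversal returning every simple path (no repeated
#' node) from `sourceNode` to `targetNode` whose edge sequence types match the
#' metapath. Edges in `masked` are treated as absent, both for traversal and
#' for the path-degree annotation: each returned path carries the
#' metaedge-specific degrees of both endpoints of every edge (`2 * length`
#' values), computed on the masked network.
#'
#' @param hetnet a [HetNet-class].
#' @param sourceNode,targetNode node identifiers whose metanodes must match
#'   the metapath endpoints.
#' @param metapath a [MetaPath-class].
#' @param masked character vector of canonical edge keys (see [edgeKey()]).
#' @return a list of paths; each a list with elements `nodes` (character),
#'   `edges` (canonical edge keys) and `degrees` (numeric, `2 * length`).
#' @export
extractPaths <- function(hetnet, sourceNode, targetNode, metapath,
                         masked = character()) {
  nd <- hetnet@nodes
  sType <- nd$metanode[match(sourceNode, nd$identifier)]
  tType <- nd$metanode[match(targetNode, nd$identifier)]
  if (is.na(sType)) stopf("unknown node: %s", sourceNode)
  if (is.na(tType)) stopf("unknown node: %s", targetNode)
  L <- length(metapath@metaedgeIds)
  if (sType != metapath@metanodeIds[1] ||
      tType != metapath@metanodeIds[L + 1])
    stopf("node metanodes (%s, %s) do not match metapath %s endpoints",
          sType, tType, metaPathAbbrev(metapath))
  out <- list()
  descend <- function(nodesSoFar, step) {
    cur <- nodesSoFar[length(nodesSoFar)]
    meId <- metapath@metaedgeIds[step]
    nbrs <- hnNeighbors(hetnet, cur, meId, masked)
    if (step == L) {
      # final step must land exactly on the target, which may not have been
      # visited already (paths with duplicate nodes are excluded)
      if (targetNode %in% nbrs && !targetNode %in% nodesSoFar)
        out[[length(out) + 1]] <<- c(nodesSoFar, targetNode)
      return(invisible(NULL))
    }
    # adjacency already restricts typed metaedges to the declared endpoint
    # metanode; same-type metaedges need no further filtering either
    nbrs <- setdiff(nbrs, nodesSoFar)
    for (v in nbrs) descend(c(nodesSoFar, v), step + 1)
  }
  descend(sourceNode, 1)
  lapply(out, function(nodesSeq) {
    eKeys <- character(L)
    degs <- numeric(2 * L)
    for (i in seq_len(L)) {
      meId <- metapath@metaedgeIds[i]
      eKeys[i] <- edgeKey(hetnet, nodesSeq[i], nodesSeq[i + 1], meId)
      degs[2 * i - 1] <- nodeDegree(hetnet, nodesSeq[i], meId, masked)
      degs[2 * i] <- nodeDegree(hetnet, nodesSeq[i + 1], meId, masked)
    }
    list(nodes = nodesSeq, edges = eKeys, metapath = metaPathAbbrev(metapath),
         degrees = degs)
  })
}
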