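# Independent brute-force reference implementations used as oracles.
# These work directly on the node/edge data frames by exhaustive table
# scanning -- no adjacency index, no shared traversal code with the package.

# masked: data.frame(source, metaedge, target) in either orientation
oracleDropMasked <- function(eg, masked) {
  if (is.null(masked) || nrow(masked) == 0) return(eg)
  bad <- rep(FALSE, nrow(eg))
  for (i in seq_len(nrow(masked))) {
    bad <- bad | (eg$metaedge == masked$metaedge[i] &
                    ((eg$source == masked$source[i] & eg$target == masked$target[i]) |
                       (eg$source == masked$target[i] & eg$target == masked$source[i])))
  }
  eg[!bad, , drop = FALSE]
}

# every simple path (node sequence) from s to t whose edges follow meIds
oraclePaths <- function(h, s, t, meIds, masked = NULL) {
  eg <- oracleDropMasked(edges(h), masked)
  found <- list()
  recurse <- function(seq_) {
    step <- length(seq_)
    cur <- seq_[step]
    rows <- which(eg$metaedge == meIds[step] &
                    (eg$source == cur | eg$target == cur))
    for (r in rows) {
      nxt <- if (eg$source[r] == cur) eg$target[r] else eg$source[r]
      if (nxt %in% seq_) next
      if (step == length(meIds)) {
        if (nxt == t) found[[length(found) + 1]] <<- c(seq_, nxt)
      } else {
        recurse(c(seq_, nxt))
      }
    }
  }
  recurse(s)
  found
}

oracleDegree <- function(h, node, meId, masked = NULL) {
  eg <- oracleDropMasked(edges(h), masked)
  sum(eg$metaedge == meId & (eg$source == node | eg$target == node))
}

oraclePC <- function(h, s, t, meIds, masked = NULL) {
  length(oraclePaths(h, s, t, meIds, masked))
}

oracleDWPC <- function(h, s, t, meIds, w, masked = NULL) {
  paths <- oraclePaths(h, s, t, meIds, masked)
  if (!length(paths)) return(0)
  sum(vapply(paths, function(p) {
    degs <- unlist(lapply(seq_along(meIds), function(i)
      c(oracleDegree(h, p[i], meIds[i], masked),
        oracleDegree(h, p[i + 1], meIds[i], masked))))
    prod(degs^(-w))
  }, 0))
}

oracleNPC <- function(h, s, t, meIds, srcType, tgtType, masked = NULL) {
  num <- oraclePC(h, s, t, meIds, masked)
  if (num == 0) return(0)
  nd <- nodes(h)
  den <- sum(vapply(nd$identifier[nd$metanode == tgtType], function(ti)
    oraclePC(h, s, ti, meIds, masked), 0)) +
    sum(vapply(nd$identifier[nd$metanode == srcType], function(si)
      oraclePC(h, si, t, meIds, masked), 0))
  if (den == 0) 0 else num / den
}

# metaedge-id sequence of a MetaPath, for feeding the oracle
mpIds <- function(mp) mp@metaedgeIds
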