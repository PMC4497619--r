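#' @include hetnet.R
NULL

# XSwap the edges of a single metaedge in place. `edges` is the canonical
# two-column matrix of endpoints; returns the swapped matrix plus bookkeeping.
# Draws are made from the current RNG stream.
xswapMetaedge <- function(edgesMat, sameType, multiplier) {
  n <- nrow(edgesMat)
  attempts <- round(multiplier * n)
  report <- c(attempts = attempts, accepted = 0, rejSelf = 0, rejDup = 0,
              rejSame = 0)
  if (n == 0 || attempts == 0)
    return(list(edges = edgesMat, report = report))
  seen <- new.env(hash = TRUE, parent = emptyenv())
  keyOf <- function(u, v) {
    if (sameType && u > v) paste(v, u, sep = "|") else paste(u, v, sep = "|")
  }
  for (i in seq_len(n))
    assign(keyOf(edgesMat[i, 1], edgesMat[i, 2]), TRUE, envir = seen)
  for (k in seq_len(attempts)) {
    ij <- sample.int(n, 2, replace = TRUE)
    if (ij[1] == ij[2]) { report["rejSame"] <- report["rejSame"] + 1; next }
    a <- edgesMat[ij[1], 1]; b <- edgesMat[ij[1], 2]
    c_ <- edgesMat[ij[2], 1]; d <- edgesMat[ij[2], 2]
    if (sameType) {
      # endpoint roles are a storage artifact for same-type undirected edges:
      # choose them uniformly before switching targets
      if (stats::runif(1) < 0.5) { tmp <- a; a <- b; b <- tmp }
      if (stats::runif(1) < 0.5) { tmp <- c_; c_ <- d; d <- tmp }
    }
    # switch the target nodes: (a-b, c-d) -> (a-d, c-b)
    if (a == d || c_ == b) { report["rejSelf"] <- report["rejSelf"] + 1; next }
    k1 <- keyOf(a, d); k2 <- keyOf(c_, b)
    if (k1 == k2 || exists(k1, envir = seen, inherits = FALSE) ||
        exists(k2, envir = seen, inherits = FALSE)) {
      report["rejDup"] <- report["rejDup"] + 1; next
    }
    rm(list = c(keyOf(a, b), keyOf(c_, d)), envir = seen)
    assign(k1, TRUE, envir = seen)
    assign(k2, TRUE, envir = seen)
    if (sameType) {
      edgesMat[ij[1], ] <- if (a <= d) c(a, d) else c(d, a)
      edgesMat[ij[2], ] <- if (c_ <= b) c(c_, b) else c(b, c_)
    } else {
      edgesMat[ij[1], ] <- c(a, d)
      edgesMat[ij[2], ] <- c(c_, b)
    }
    report["accepted"] <- report["accepted"] + 1
  }
  list(edges = edgesMat, report = report)
}

#' Degree-preserving network permutation (XSwap)
#'
#' Randomizes a hetnet by swapping edges separately for each metaedge:
#' repeatedly pick two edges of the metaedge at random and switch their
#' target nodes. Per metaedge, the number of attempted swaps is `multiplier`
#' times its edge count. A proposed swap is rejected -- while still counting
#' toward the attempt budget -- if it would create a self-loop or a duplicate
#' edge, or if the two draws picked the same edge. Every node's
#' metaedge-specific degree is exactly preserved, so permuted networks retain
#' degree-driven (unspecific) signal only.
#'
#' @param hetnet a [HetNet-class].
#' @param multiplier attempted swaps per edge (default 10).
#' @param seed integer seed; the permutation is deterministic given the seed.
#'   `NULL` draws from the current RNG state (used by [permutationChain()]).
#' @return a list with elements `hetnet` (the permuted network) and `report`
#'   (data.frame per metaedge: edge count, attempts, accepted swaps, and
#'   rejection counts by reason, plus the seed).
#' @export
permuteNetwork <- function(hetnet, multiplier = 10, seed = 0) {
  run <- function() {
    me <- hetnet@metagraph@metaedges
    ids <- sort(me$id)
    eg <- hetnet@edges
    outEdges <- list()
    reports <- list()
    for (id in ids) {
      sub <- eg[eg$metaedge == id, , drop = FALSE]
      sameType <- me$source[me$id == id] == me$target[me$id == id]
      res <- xswapMetaedge(as.matrix(sub[, c("source", "target")]), sameType,
                           multiplier)
      sub$source <- res$edges[, 1]
      sub$target <- res$edges[, 2]
      sub$weight <- rep(NA_real_, nrow(sub))
      outEdges[[id]] <- sub
      reports[[id]] <- data.frame(metaedge = id, nEdges = nrow(sub),
                                  t(res$report))
    }
    eg2 <- do.call(rbind, c(outEdges,
                            list(eg[!eg$metaedge %in% ids, , drop = FALSE])))
    rownames(eg2) <- NULL
    net <- new("HetNet", metagraph = hetnet@metagraph, nodes = hetnet@nodes,
               edges = eg2,
               adjacency = buildAdjacency(hetnet@metagraph, hetnet@nodes, eg2))
    validObject(net)
    report <- if (length(reports)) do.call(rbind, reports) else
      data.frame(metaedge = character(0), nEdges = integer(0),
                 attempts = integer(0), accepted = integer(0),
                 rejSelf = integer(0), rejDup = integer(0),
                 rejSame = integer(0))
    rownames(report) <- NULL
    report$seed <- if (is.null(seed)) NA_integer_ else seed
    list(hetnet = net, report = report)
  }
  if (is.null(seed)) run() else withSeed(seed, run())
}

#' Markov chain of permuted networks
#'
#' Produces `nNetworks` permuted networks where each round of permutation
#' starts from the most recently permuted network, using a single seeded
#' generator for the whole chain. Every network in the chain preserves the
#' original's per-metaedge degree sequence, while successive rounds drift
#' further from the original edge set.
#'
#' @inheritParams permuteNetwork
#' @param nNetworks chain length (default 5).
#' @return a list of length `nNetworks`; each element a `permuteNetwork()`
#'   result (`hetnet` + `report`).
#' @export
permutationChain <- function(hetnet, nNetworks = 5, multiplier = 10, seed = 0) {
  stopifnot(nNetworks >= 1)
  withSeed(seed, {
    out <- vector("list", nNetworks)
    cur <- hetnet
    for (i in seq_len(nNetworks)) {
      res <- permuteNetwork(cur, multiplier, seed = NULL)
      res$report$seed <- seed
      out[[i]] <- res
      cur <- res$hetnet
    }
    out
  })
}
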