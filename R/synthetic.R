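#' @include features.R
NULL

#' A small gene-disease metagraph for simulation and examples
#'
#' Four metanodes (Gene, Disease, Tissue, Pathway) joined by five undirected
#' metaedges: association (`DaG`), localization (`DlT`), expression (`GeT`),
#' interaction (`GiG`) and pathway membership (`GmPw`). A structural
#' miniature of the bundled 18-metanode schema: it supports the same shapes
#' of gene-to-disease metapaths (tissue-routed, interactome-routed,
#' set-traversing, pleiotropy-routed).
#'
#' @return a [MetaGraph-class].
#' @export
toyMetagraph <- function() {
  buildMetaGraph(
    metanodes = data.frame(
      identifier = c("Gene", "Disease", "Tissue", "Pathway"),
      abbreviation = c("G", "D", "T", "Pw")),
    metaedges = data.frame(
      source = c("Disease", "Disease", "Gene", "Gene", "Gene"),
      target = c("Gene", "Tissue", "Tissue", "Gene", "Pathway"),
      kind = c("association", "localization", "expression", "interaction",
               "membership"),
      abbreviation = c("a", "l", "e", "i", "m")))
}

# Pareto-distributed node attractiveness for heavy-tailed degree sequences;
# exponent is the power-law tail exponent (> 1).
nodeWeights <- function(n, distribution, exponent) {
  switch(distribution,
         uniform = rep(1, n),
         powerlaw = stats::runif(n)^(-1 / (exponent - 1)),
         stopf("unknown degree distribution: %s", distribution))
}

#' Generate a random hetnet conforming to a metagraph
#'
#' For each configured metaedge, draws `round(density * nPossible)` distinct
#' node pairs (self-pairs excluded) with probability proportional to the
#' product of endpoint attractiveness weights: uniform weights give an
#' Erdos-Renyi-like block, `"powerlaw"` weights a heavy-tailed degree
#' distribution whose variance exceeds the uniform one at equal mean degree.
#'
#' @param metagraph a [MetaGraph-class].
#' @param nodeCounts named integer vector: nodes per metanode (names are
#'   metanode identifiers; all counts >= 1).
#' @param edgeParams named list keyed by metaedge id; each element a list
#'   with `density` in (0, 1] and optionally `distribution`
#'   (`"uniform"`, default, or `"powerlaw"`) and `exponent` (default 2.5).
#'   Metaedges absent from the list get no edges.
#' @param seed integer seed; generation is reproducible.
#' @return a [HetNet-class]. Node identifiers are
#'   `<metanode abbreviation><number>`, e.g. `G007`.
#' @export
generateHetNet <- function(metagraph, nodeCounts, edgeParams, seed = 0) {
  mn <- metagraph@metanodes
  if (!all(names(nodeCounts) %in% mn$identifier))
    stopf("nodeCounts names must be declared metanodes")
  if (any(nodeCounts < 1)) stopf("node counts must be >= 1")
  bad <- setdiff(names(edgeParams), metagraph@metaedges$id)
  if (length(bad)) stopf("unknown metaedge in edgeParams: %s",
                         paste(bad, collapse = ", "))
  ids <- lapply(names(nodeCounts), function(type) {
    ab <- mn$abbreviation[mn$identifier == type]
    sprintf("%s%03d", ab, seq_len(nodeCounts[[type]]))
  })
  names(ids) <- names(nodeCounts)
  nodes <- data.frame(identifier = unlist(ids, use.names = FALSE),
                      metanode = rep(names(nodeCounts),
                                     times = vapply(ids, length, 1L)),
                      stringsAsFactors = FALSE)
  nodes$name <- nodes$identifier
  me <- metagraph@metaedges
  withSeed(seed, {
    edgeTabs <- lapply(names(edgeParams), function(meId) {
      par <- edgeParams[[meId]]
      density <- par$density
      if (is.null(density) || density <= 0 || density > 1)
        stopf("metaedge %s: density must lie in (0, 1]", meId)
      distribution <- par$distribution %||% "uniform"
      exponent <- par$exponent %||% 2.5
      srcType <- me$source[me$id == meId]
      tgtType <- me$target[me$id == meId]
      if (!srcType %in% names(nodeCounts) || !tgtType %in% names(nodeCounts))
        stopf("metaedge %s endpoints lack node counts", meId)
      s <- ids[[srcType]]
      t <- ids[[tgtType]]
      if (srcType == tgtType) {
        pairIdx <- utils::combn(length(s), 2)
        cand <- data.frame(source = s[pairIdx[1, ]], target = s[pairIdx[2, ]])
        wS <- nodeWeights(length(s), distribution, exponent)
        prob <- wS[pairIdx[1, ]] * wS[pairIdx[2, ]]
      } else {
        cand <- expand.grid(source = s, target = t, stringsAsFactors = FALSE,
                            KEEP.OUT.ATTRS = FALSE)
        wS <- nodeWeights(length(s), distribution, exponent)
        wT <- nodeWeights(length(t), distribution, exponent)
        prob <- wS[match(cand$source, s)] * wT[match(cand$target, t)]
      }
      m <- round(density * nrow(cand))
      if (m == 0) return(NULL)
      pick <- sample.int(nrow(cand), m, prob = prob)
      data.frame(source = cand$source[pick], metaedge = meId,
                 target = cand$target[pick], stringsAsFactors = FALSE)
    })
    edgeTabs <- edgeTabs[!vapply(edgeTabs, is.null, TRUE)]
    edges <- if (length(edgeTabs)) do.call(rbind, edgeTabs) else NULL
    hetNet(metagraph, nodes, edges)
  })
}

#' Plant association edges with metapath-borne signal
#'
#' Adds `nPositives` edges of the prediction metaedge, drawn sequentially:
#' at each step every remaining candidate (source, target) pair is given
#' weight `effectSize^k`, where `k` is its current number of connections
#' along the signal metapaths (the sum of their path counts on the network
#' as planted so far), and one pair is sampled. Signal metapaths that end
#' with the prediction metaedge (e.g. set-traversing `GmPwmGaD`) therefore
#' feed back on earlier plantings, creating the shared-membership,
#' interaction-adjacency and pleiotropy structure the DWPC features detect.
#' `effectSize = 1` plants uniformly at random (no signal).
#'
#' With `balancedTargets = TRUE` (default) each planted edge first samples
#' its target node uniformly, so edges spread over the targets with
#' multinomial (natural) degree variance -- mirroring label sets where every
#' analyzed disease carries associations. Without it the feedback can
#' concentrate all edges on one target, which also freezes the
#' degree-preserving permutation null for that metaedge (hardly any swap is
#' legal when one node holds most edges).
#'
#' @param hetnet a [HetNet-class] (without edges of the prediction metaedge
#'   between the planted pairs).
#' @param signalMetapaths metapath abbreviations (or [MetaPath-class] list)
#'   from the source to the target metanode of the prediction metaedge.
#' @param effectSize odds multiplier per connection (>= 1).
#' @param nPositives number of association edges to plant.
#' @param predictionMetaedge metaedge id of the planted edges.
#' @param balancedTargets spread planted edges evenly over target nodes
#'   (default `TRUE`).
#' @param seed integer seed.
#' @return a list: `hetnet` (with the planted edges), `pairs` (data.frame
#'   `source`, `target`, `label` over all candidate pairs) and `effectSize`.
#' @export
plantAssociations <- function(hetnet, signalMetapaths, effectSize = 8,
                              nPositives, predictionMetaedge = "DaG",
                              balancedTargets = TRUE, seed = 0) {
  mg <- hetnet@metagraph
  config <- featureConfig(mg, predictionMetaedge)
  srcType <- config$sourceMetanode
  tgtType <- config$targetMetanode
  mps <- lapply(signalMetapaths, function(m)
    if (is.character(m)) parseMetaPath(mg, m) else m)
  for (mp in mps) {
    if (mp@metanodeIds[1] != srcType ||
        mp@metanodeIds[length(mp@metanodeIds)] != tgtType)
      stopf("signal metapath %s does not join %s to %s",
            metaPathAbbrev(mp), srcType, tgtType)
  }
  dynamic <- vapply(mps, function(mp)
    predictionMetaedge %in% mp@metaedgeIds, TRUE)
  nd <- hetnet@nodes
  cand <- expand.grid(source = nd$identifier[nd$metanode == srcType],
                      target = nd$identifier[nd$metanode == tgtType],
                      stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  if (nPositives > nrow(cand))
    stopf("requested %d positives but only %d candidate pairs",
          nPositives, nrow(cand))
  countFor <- function(net, idx, which) {
    vapply(idx, function(r) sum(vapply(mps[which], function(mp)
      pathCount(net, cand$source[r], cand$target[r], mp), 0)), 0)
  }
  withSeed(seed, {
    net <- hetnet
    open <- seq_len(nrow(cand))
    staticCounts <- countFor(net, seq_len(nrow(cand)), !dynamic)
    targets <- unique(cand$target)
    chosen <- integer(0)
    for (k in seq_len(nPositives)) {
      pool <- open
      if (balancedTargets) {
        # uniform multinomial over targets: no target hogs the edges, but
        # target degrees keep natural sampling variance
        avail <- unique(cand$target[open])
        tgt <- avail[sample.int(length(avail), 1)]
        pool <- open[cand$target[open] == tgt]
      }
      counts <- staticCounts[pool]
      if (any(dynamic))
        counts <- counts + countFor(net, pool, dynamic)
      pick <- pool[sample.int(length(pool), 1, prob = effectSize^counts)]
      chosen <- c(chosen, pick)
      open <- setdiff(open, pick)
      newEdge <- data.frame(source = cand$source[pick],
                            metaedge = predictionMetaedge,
                            target = cand$target[pick],
                            stringsAsFactors = FALSE)
      eg <- rbind(net@edges[, c("source", "metaedge", "target")], newEdge)
      net <- hetNet(mg, net@nodes, eg)
    }
    cand$label <- as.integer(seq_len(nrow(cand)) %in% chosen)
    list(hetnet = net, pairs = cand, effectSize = effectSize)
  })
}

#' Deterministic micro-fixtures
#'
#' Three hand-constructed toy networks (on the [toyMetagraph()] schema) with
#' known path structure, each bundled with its probe pair:
#' \describe{
#'   \item{`fig2like`}{the probe pair is joined by exactly one
#'     tissue-routed `GeTlD` path and two interactome-routed `GiGaD` paths,
#'     plus its own association edge (so masking is exercised).}
#'   \item{`hub`}{two candidate genes with identical path counts to the
#'     disease, one routed through a hub: for any `w > 0` the DWPC ranks
#'     the specific gene strictly higher.}
#'   \item{`masked`}{a positive pair whose only connection is its own
#'     association edge: after masking, every feature is 0 except the
#'     polygenicity count.}
#' }
#'
#' @return a named list; each element a list with `hetnet` and `probe`
#'   (named character vector `source`, `target`).
#' @export
microFixtures <- function() {
  mg <- toyMetagraph()
  mk <- function(geneIds, diseaseIds, tissueIds, edges) {
    nodes <- data.frame(
      identifier = c(geneIds, diseaseIds, tissueIds),
      metanode = c(rep("Gene", length(geneIds)),
                   rep("Disease", length(diseaseIds)),
                   rep("Tissue", length(tissueIds))),
      stringsAsFactors = FALSE)
    hetNet(mg, nodes, edges)
  }
  fig2like <- mk(
    c("G1", "G2", "G3"), c("D1", "D2"), "T1",
    data.frame(
      source = c("G1", "T1", "G1", "G1", "G2", "G3", "G1"),
      metaedge = c("GeT", "DlT", "GiG", "GiG", "DaG", "DaG", "DaG"),
      target = c("T1", "D1", "G2", "G3", "D1", "D1", "D1"),
      stringsAsFactors = FALSE))
  hub <- mk(
    c("GA", "GB", "Gs", "Gh", "H1", "H2", "H3"), "D1", character(0),
    data.frame(
      source = c("GA", "Gs", "GB", "Gh", "Gh", "Gh", "Gh"),
      metaedge = c("GiG", "DaG", "GiG", "DaG", "GiG", "GiG", "GiG"),
      target = c("Gs", "D1", "Gh", "D1", "H1", "H2", "H3"),
      stringsAsFactors = FALSE))
  masked <- mk(
    c("G1", "G2"), "D1", character(0),
    data.frame(source = c("G1", "G2"), metaedge = c("DaG", "DaG"),
               target = c("D1", "D1"), stringsAsFactors = FALSE))
  list(
    fig2like = list(hetnet = fig2like, probe = c(source = "G1", target = "D1")),
    hub = list(hetnet = hub, probe = c(source = "GA", target = "D1")),
    masked = list(hetnet = masked, probe = c(source = "G1", target = "D1")))
}
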