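#' @include metapath.R
NULL

#' Path count
#'
#' The number of simple paths between two nodes instantiating a metapath,
#' with edges in `masked` treated as absent.
#'
#' @inheritParams extractPaths
#' @return a non-negative integer.
#' @export
pathCount <- function(hetnet, sourceNode, targetNode, metapath,
                      masked = character()) {
  length(extractPaths(hetnet, sourceNode, targetNode, metapath, masked))
}

#' Path-degree product
#'
#' The specificity of a single path: the product over its metaedge-specific
#' endpoint degrees (two per edge) of each degree raised to `-w`. High-degree
#' (hub-routed) paths receive small products; `w = 0` makes every path worth
#' exactly 1.
#'
#' @param path a path as returned by [extractPaths()] (needs a `degrees`
#'   element), or a bare numeric vector of degrees.
#' @param w damping exponent, `w >= 0`.
#' @return a positive real.
#' @examples
#' pathDegreeProduct(c(4, 2), w = 0.5)  # 8^-0.5
#' @export
pathDegreeProduct <- function(path, w) {
  if (w < 0) stopf("damping exponent w must be non-negative")
  degs <- if (is.list(path)) path$degrees else path
  if (any(degs < 1))
    stopf("inconsistent path degrees: every traversed edge implies degree >= 1")
  prod(degs^(-w))
}

#' Degree-weighted path count
#'
#' The sum of path-degree products over all simple paths of a metapath
#' between two nodes; 0 when no paths connect them. Equals [pathCount()]
#' exactly when `w = 0`.
#'
#' @inheritParams extractPaths
#' @param w damping exponent, `w >= 0`.
#' @return a non-negative real.
#' @export
dwpc <- function(hetnet, sourceNode, targetNode, metapath, w = 0.4,
                 masked = character()) {
  paths <- extractPaths(hetnet, sourceNode, targetNode, metapath, masked)
  if (length(paths) == 0) return(0)
  sum(vapply(paths, pathDegreeProduct, 0, w = w))
}

#' Normalized path count
#'
#' [pathCount()] for the probe pair divided by the total count of metapath
#' instances from the source to any node of the target metanode plus from
#' any node of the source metanode to the target. Defined as 0 when the
#' denominator is 0 (no connectivity means no evidence).
#'
#' @inheritParams extractPaths
#' @return a real in `[0, 1]`.
#' @export
npc <- function(hetnet, sourceNode, targetNode, metapath,
                masked = character()) {
  num <- pathCount(hetnet, sourceNode, targetNode, metapath, masked)
  if (num == 0) return(0)
  nd <- hetnet@nodes
  L <- length(metapath@metaedgeIds)
  targets <- nd$identifier[nd$metanode == metapath@metanodeIds[L + 1]]
  sources <- nd$identifier[nd$metanode == metapath@metanodeIds[1]]
  den <- sum(vapply(targets, function(ti)
    pathCount(hetnet, sourceNode, ti, metapath, masked), 0)) +
    sum(vapply(sources, function(si)
      pathCount(hetnet, si, targetNode, metapath, masked), 0))
  if (den == 0) return(0)
  num / den
}

#' Pleiotropy and polygenicity counts
#'
#' The two non-DWPC ("path count") features: `pleiotropyCount()` is the
#' number of target-type nodes linked to the source by the prediction
#' metaedge (diseases associated with the source gene); `polygenicityCount()`
#' the number of source-type nodes linked to the target (genes associated
#' with the target disease). Both are metaedge degrees on the masked network,
#' so a pair's own association edge never contributes.
#'
#' @param hetnet a [HetNet-class].
#' @param node node identifier (the source gene, resp. target disease).
#' @param associationMetaedge id of the prediction metaedge.
#' @param masked canonical edge keys treated as absent.
#' @return a non-negative integer.
#' @export
pleiotropyCount <- function(hetnet, node, associationMetaedge,
                            masked = character()) {
  nodeDegree(hetnet, node, associationMetaedge, masked)
}

#' @rdname pleiotropyCount
#' @export
polygenicityCount <- function(hetnet, node, associationMetaedge,
                              masked = character()) {
  nodeDegree(hetnet, node, associationMetaedge, masked)
}

#' Feature configuration for a prediction metaedge
#'
#' Enumerates the DWPC feature metapaths for predicting a metaedge: all
#' metapaths of length `maxLength` or less from the prediction metaedge's
#' gene-side (source) metanode to its disease-side (target) metanode,
#' excluding the bare single-edge metapath consisting of the prediction
#' metaedge alone, which is identically zero once each probe pair's own edge
#' is masked. Adds the two path-count features.
#'
#' @param metagraph a [MetaGraph-class].
#' @param predictionMetaedge metaedge id being predicted (e.g. `"DaG"`).
#' @param sourceMetanode metanode where metapaths originate (the gene side);
#'   defaults to the prediction metaedge's *target* endpoint if that endpoint
#'   is named `"Gene"`, otherwise to the metaedge's source endpoint.
#' @param w damping exponent (default 0.4, the cross-validated optimum for
#'   the bundled gene-disease schema).
#' @param maxLength maximum metapath length (default 3).
#' @return a list with elements `metapaths` (list of [MetaPath-class], in
#'   deterministic length-then-abbreviation order), `featureNames`,
#'   `predictionMetaedge`, `sourceMetanode`, `targetMetanode`, `w`.
#' @export
featureConfig <- function(metagraph, predictionMetaedge, sourceMetanode = NULL,
                          w = 0.4, maxLength = 3) {
  me <- metagraph@metaedges
  row <- me[me$id == predictionMetaedge, ]
  if (nrow(row) != 1) stopf("unknown prediction metaedge: %s", predictionMetaedge)
  if (is.null(sourceMetanode))
    sourceMetanode <- if (row$target == "Gene") row$target else row$source
  targetMetanode <- setdiff(c(row$source, row$target), sourceMetanode)
  if (length(targetMetanode) == 0) targetMetanode <- sourceMetanode
  mps <- enumerateMetaPaths(metagraph, sourceMetanode, targetMetanode, maxLength)
  bare <- vapply(mps, function(mp)
    length(mp) == 1 && mp@metaedgeIds[1] == predictionMetaedge, TRUE)
  mps <- mps[!bare]
  abbrevs <- vapply(mps, metaPathAbbrev, "")
  srcSide <- metaPathAbbrev(metaPathFromIds(metagraph, sourceMetanode,
                                            predictionMetaedge))
  tgtSide <- metaPathAbbrev(metaPathFromIds(metagraph, targetMetanode,
                                            predictionMetaedge))
  countNames <- c(
    sprintf("PC_%s_any_%s", srcSide, tolower(gsub("[^A-Za-z0-9]", "",
                                                  targetMetanode))),
    sprintf("PC_%s_any_%s", tgtSide, tolower(gsub("[^A-Za-z0-9]", "",
                                                  sourceMetanode))))
  list(metapaths = mps,
       featureNames = c(paste0("DWPC_", abbrevs), countNames),
       predictionMetaedge = predictionMetaedge,
       sourceMetanode = sourceMetanode, targetMetanode = targetMetanode,
       w = w, maxLength = maxLength)
}

#' Compute the feature matrix for labeled pairs
#'
#' One row per (source, target) pair; columns are the DWPC feature for each
#' configured metapath plus the two path-count features, in deterministic
#' order. For each row, only that pair's own prediction edge (if present) is
#' masked before any feature -- including the degrees entering the DWPC and
#' the two counts -- is computed, so a positive pair is scored exactly as if
#' its edge had never been in the network.
#'
#' @param hetnet a [HetNet-class].
#' @param pairs data.frame with columns `source`, `target` and optionally
#'   `label` (0/1).
#' @param config a [featureConfig()] list.
#' @return a data.frame `source`, `target`, `label`, then one numeric column
#'   per feature; the configuration is attached as attribute `"config"`.
#' @export
computeFeatureMatrix <- function(hetnet, pairs, config) {
  nd <- hetnet@nodes
  badS <- setdiff(pairs$source, nd$identifier)
  badT <- setdiff(pairs$target, nd$identifier)
  if (length(badS) || length(badT))
    stopf("pair(s) reference unknown node(s): %s",
          paste(unique(c(badS, badT)), collapse = ", "))
  mps <- config$metapaths
  nFeat <- length(config$featureNames)
  X <- matrix(0, nrow(pairs), nFeat,
              dimnames = list(NULL, config$featureNames))
  eg <- hetnet@edges
  eKeys <- edgeKeyString(eg$source, eg$metaedge, eg$target)
  for (r in seq_len(nrow(pairs))) {
    s <- pairs$source[r]; t <- pairs$target[r]
    key <- edgeKey(hetnet, s, t, config$predictionMetaedge)
    maskedR <- if (key %in% eKeys) key else character(0)
    for (j in seq_along(mps))
      X[r, j] <- dwpc(hetnet, s, t, mps[[j]], w = config$w, masked = maskedR)
    X[r, nFeat - 1] <- pleiotropyCount(hetnet, s, config$predictionMetaedge,
                                       maskedR)
    X[r, nFeat] <- polygenicityCount(hetnet, t, config$predictionMetaedge,
                                     maskedR)
  }
  out <- data.frame(source = pairs$source, target = pairs$target,
                    label = if ("label" %in% names(pairs))
                      as.integer(pairs$label) else NA_integer_,
                    stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(X, check.names = FALSE))
  attr(out, "config") <- config
  out
}

# Names of the feature columns of a feature matrix data.frame.
featureColumns <- function(featureMatrix) {
  setdiff(names(featureMatrix), c("source", "target", "label"))
}
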