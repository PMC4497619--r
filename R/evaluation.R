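#' @include modeling.R
NULL

checkScored <- function(scores, labels) {
  if (length(scores) != length(labels))
    stopf("scores and labels must have equal length")
  labels <- as.integer(labels)
  if (!all(labels %in% c(0L, 1L))) stopf("labels must be binary 0/1")
  if (length(unique(labels)) < 2)
    stopf("both classes must be present")
  labels
}

#' Area under the ROC curve
#'
#' The probability that a randomly chosen positive outscores a randomly
#' chosen negative, ties counted half (the rank / Mann-Whitney formulation).
#'
#' @param scores numeric predictions (higher = more positive).
#' @param labels binary 0/1 labels.
#' @return a real in `[0, 1]`.
#' @export
auroc <- function(scores, labels) {
  labels <- checkScored(scores, labels)
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC curve points
#'
#' FPR/TPR at every distinct score threshold (ties grouped), from (0, 0) to
#' (1, 1), thresholds decreasing.
#'
#' @inheritParams auroc
#' @return data.frame: `threshold`, `fpr`, `tpr`.
#' @export
rocCurve <- function(scores, labels) {
  labels <- checkScored(scores, labels)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  cumTp <- cumsum(y)
  cumFp <- cumsum(1 - y)
  idx <- which(!duplicated(s, fromLast = TRUE))
  data.frame(threshold = c(Inf, s[idx]),
             fpr = c(0, cumFp[idx] / sum(y == 0)),
             tpr = c(0, cumTp[idx] / sum(y == 1)))
}

#' Precision-recall curve and precision at a recall level
#'
#' `precisionRecallCurve()` evaluates precision and recall at every distinct
#' score threshold (ties grouped, thresholds decreasing).
#' `precisionAtRecall()` returns the precision at the highest threshold whose
#' recall reaches at least `recallLevel`. At the boundary `recallLevel = 1`
#' the threshold is taken at the minimum score -- every pair is predicted
#' positive -- so the precision equals the prevalence exactly (trailing
#' negatives below the last positive would otherwise inflate it).
#'
#' @inheritParams auroc
#' @return data.frame: `threshold`, `recall`, `precision`.
#' @export
precisionRecallCurve <- function(scores, labels) {
  labels <- checkScored(scores, labels)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  idx <- which(!duplicated(s, fromLast = TRUE))
  cumTp <- cumsum(y)[idx]
  n <- seq_along(s)[idx]
  data.frame(threshold = s[idx], recall = cumTp / sum(y == 1),
             precision = cumTp / n)
}

#' @rdname precisionRecallCurve
#' @param recallLevel target recall in `(0, 1]`.
#' @return `precisionAtRecall()`: a single precision value.
#' @export
precisionAtRecall <- function(scores, labels, recallLevel) {
  if (recallLevel <= 0 || recallLevel > 1)
    stopf("recallLevel must lie in (0, 1]")
  pr <- precisionRecallCurve(scores, labels)
  if (recallLevel == 1) return(pr$precision[nrow(pr)])
  hit <- which(pr$recall >= recallLevel)
  if (!length(hit)) stopf("recall level %g not reachable", recallLevel)
  pr$precision[hit[1]]
}

#' Area under the precision-recall curve
#'
#' Trapezoidal integration of the precision-recall points.
#'
#' @inheritParams auroc
#' @return a real in `[0, 1]`.
#' @export
auprc <- function(scores, labels) {
  pr <- precisionRecallCurve(scores, labels)
  rec <- c(0, pr$recall)
  prec <- c(pr$precision[1], pr$precision)
  sum(diff(rec) * (utils::head(prec, -1) + utils::tail(prec, -1)) / 2)
}

#' Fold enrichment of precision over prevalence
#'
#' How many times the observed precision exceeds the precision expected when
#' every pair is equally likely a priori (the positive prevalence).
#'
#' @param precision observed precision.
#' @param prevalence positive prevalence (> 0).
#' @return precision / prevalence.
#' @examples
#' foldEnrichment(0.167, 698 / (698 + 551823))  # ~132
#' @export
foldEnrichment <- function(precision, prevalence) {
  if (prevalence <= 0) stopf("prevalence must be positive")
  precision / prevalence
}

#' Exponential CROC transform of the false-positive-rate axis
#'
#' The concentrated-ROC transform `f(x) = (1 - exp(-a x)) / (1 - exp(-a))`
#' magnifies the early (low-FPR) part of the ROC curve. `f(0) = 0` and
#' `f(1) = 1` for any magnification `a > 0`; as `a -> 0` the transform tends
#' to the identity. The default `a = 460` maps FPR 0.01 to ~0.99,
#' concentrating on the top 1% of predictions (the exact solution of
#' `f(0.01) = 0.99` is `100 * log(100) ~ 460.5`).
#'
#' @param fpr numeric vector of false positive rates in `[0, 1]`.
#' @param magnification magnification factor `a > 0` (default 460).
#' @return transformed values in `[0, 1]`.
#' @export
crocTransform <- function(fpr, magnification = 460) {
  if (magnification <= 0) stopf("magnification must be positive")
  (1 - exp(-magnification * fpr)) / (1 - exp(-magnification))
}

#' Concentrated ROC curve and area
#'
#' The ROC curve with the FPR axis transformed by [crocTransform()];
#' `crocArea()` integrates it by the trapezoid rule over the transformed
#' points.
#'
#' @inheritParams auroc
#' @inheritParams crocTransform
#' @return `crocCurve()`: data.frame `threshold`, `fpr` (transformed), `tpr`;
#'   `crocArea()`: a real in `[0, 1]`.
#' @export
crocCurve <- function(scores, labels, magnification = 460) {
  roc <- rocCurve(scores, labels)
  roc$fpr <- crocTransform(roc$fpr, magnification)
  roc
}

#' @rdname crocCurve
#' @export
crocArea <- function(scores, labels, magnification = 460) {
  cc <- crocCurve(scores, labels, magnification)
  sum(diff(cc$fpr) * (utils::head(cc$tpr, -1) + utils::tail(cc$tpr, -1)) / 2)
}

# DeLong variance of a single AUROC estimate via structural components.
delongVariance <- function(scores, labels) {
  labels <- checkScored(scores, labels)
  xs <- scores[labels == 1]
  ys <- scores[labels == 0]
  m <- length(xs); n <- length(ys)
  psi <- outer(xs, ys, function(x, y) (x > y) + 0.5 * (x == y))
  v10 <- rowMeans(psi)
  v01 <- colMeans(psi)
  theta <- mean(psi)
  list(auc = theta,
       var = stats::var(v10) / m + stats::var(v01) / n)
}

#' One-sided unpaired DeLong test for two AUROCs
#'
#' Tests whether the AUROC of classifier A exceeds that of classifier B when
#' the two score/label sets are independent (e.g. the same features computed
#' on the real versus a permuted network). The variance of the difference is
#' the sum of the two independent DeLong variances.
#'
#' @param scoresA,labelsA scores and 0/1 labels for classifier A.
#' @param scoresB,labelsB scores and 0/1 labels for classifier B.
#' @param alternative `"greater"` (default; H1: AUROC_A > AUROC_B),
#'   `"less"`, or `"two.sided"`.
#' @return a list: `aucA`, `aucB`, `z`, `pValue`.
#' @export
delongTestUnpaired <- function(scoresA, labelsA, scoresB, labelsB,
                               alternative = c("greater", "less", "two.sided")) {
  alternative <- match.arg(alternative)
  a <- delongVariance(scoresA, labelsA)
  b <- delongVariance(scoresB, labelsB)
  se <- sqrt(a$var + b$var)
  z <- if (se == 0) 0 else (a$auc - b$auc) / se
  p <- switch(alternative,
              greater = stats::pnorm(z, lower.tail = FALSE),
              less = stats::pnorm(z),
              two.sided = 2 * stats::pnorm(abs(z), lower.tail = FALSE))
  list(aucA = a$auc, aucB = b$auc, z = z, pValue = p)
}

#' Per-feature and per-group AUROCs
#'
#' Treats each feature column of a labeled feature matrix as a classifier:
#' global AUROC over all pairs pooled, and (optionally) AUROC within each
#' group (e.g. disease). Groups where only one class is present are skipped
#' with a note in the `skipped` attribute.
#'
#' @param featureMatrix a [computeFeatureMatrix()] result (needs `label`).
#' @param perGroup column used for grouping (default `"target"`); `NULL`
#'   disables the per-group table.
#' @return a list: `global` (data.frame `feature`, `auroc`) and `byGroup`
#'   (data.frame `feature`, `group`, `auroc`, possibly empty).
#' @export
featurePerformance <- function(featureMatrix, perGroup = "target") {
  feats <- featureColumns(featureMatrix)
  y <- featureMatrix$label
  global <- data.frame(feature = feats,
                       auroc = vapply(feats, function(f)
                         auroc(featureMatrix[[f]], y), 0),
                       row.names = NULL)
  byGroup <- data.frame(feature = character(0), group = character(0),
                        auroc = numeric(0))
  skipped <- character(0)
  if (!is.null(perGroup)) {
    for (g in unique(featureMatrix[[perGroup]])) {
      sel <- featureMatrix[[perGroup]] == g
      if (length(unique(y[sel])) < 2) { skipped <- c(skipped, g); next }
      byGroup <- rbind(byGroup, data.frame(
        feature = feats, group = g,
        auroc = vapply(feats, function(f)
          auroc(featureMatrix[[f]][sel], y[sel]), 0), row.names = NULL))
    }
  }
  attr(byGroup, "skipped") <- skipped
  list(global = global, byGroup = byGroup)
}

#' Gene-set subsampling robustness
#'
#' Masks an increasing percentage of a gene-set collection -- either its
#' nodes (with all their membership edges) or its membership edges, without
#' replacement -- and tracks the AUROC of the affected set-traversing DWPC
#' feature (`Gm{set}mGaD`-shaped) on the evaluation pairs.
#'
#' @param hetnet a [HetNet-class].
#' @param setMetanode the collection metanode; it must participate in exactly
#'   one membership metaedge.
#' @param scheme `"node"` or `"edge"` masking.
#' @param percentages numeric vector of masking percentages in `[0, 100]`.
#' @param repetitions subsampling repetitions per percentage (default 10).
#' @param seed integer seed.
#' @param pairs labeled evaluation pairs.
#' @param predictionMetaedge metaedge id of the labels (e.g. `"DaG"`).
#' @param w damping exponent (default 0.4).
#' @return data.frame: `percentage`, `repetition`, `auroc`.
#' @export
subsampleGeneSet <- function(hetnet, setMetanode,
                             scheme = c("node", "edge"), percentages,
                             repetitions = 10, seed = 0, pairs,
                             predictionMetaedge, w = 0.4) {
  scheme <- match.arg(scheme)
  if (any(percentages < 0 | percentages > 100))
    stopf("percentages must lie in [0, 100]")
  mg <- hetnet@metagraph
  me <- mg@metaedges
  inc <- me[me$source == setMetanode | me$target == setMetanode, ]
  if (nrow(inc) != 1)
    stopf("metanode %s must participate in exactly one membership metaedge",
          setMetanode)
  memberId <- inc$id
  geneSide <- setdiff(c(inc$source, inc$target), setMetanode)
  mp <- metaPathFromIds(mg, geneSide,
                        c(memberId, memberId, predictionMetaedge))
  eg <- hetnet@edges
  memberEdges <- which(eg$metaedge == memberId)
  setNodes <- hetnet@nodes$identifier[hetnet@nodes$metanode == setMetanode]
  featAuroc <- function(net) {
    vals <- vapply(seq_len(nrow(pairs)), function(r) {
      key <- edgeKey(net, pairs$source[r], pairs$target[r], predictionMetaedge)
      inNet <- key %in% edgeKeyString(net@edges$source, net@edges$metaedge,
                                      net@edges$target)
      dwpc(net, pairs$source[r], pairs$target[r], mp, w = w,
           masked = if (inNet) key else character(0))
    }, 0)
    auroc(vals, pairs$label)
  }
  withSeed(seed, {
    out <- list()
    for (pct in percentages) for (rep_ in seq_len(repetitions)) {
      if (scheme == "node") {
        drop <- sample(setNodes, round(pct / 100 * length(setNodes)))
        dropIdx <- memberEdges[eg$source[memberEdges] %in% drop |
                                 eg$target[memberEdges] %in% drop]
      } else {
        dropIdx <- sample(memberEdges,
                          round(pct / 100 * length(memberEdges)))
      }
      keys <- edgeKeyString(eg$source[dropIdx], eg$metaedge[dropIdx],
                            eg$target[dropIdx])
      out[[length(out) + 1]] <- data.frame(
        percentage = pct, repetition = rep_,
        auroc = featAuroc(removeEdges(hetnet, keys)))
    }
    do.call(rbind, out)
  })
}
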