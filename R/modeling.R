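#' @include features.R
NULL

# Stratified fold assignment: each class is spread evenly across folds.
# Uses the current RNG stream.
stratifiedFolds <- function(y, nFolds) {
  foldid <- integer(length(y))
  for (cls in unique(y)) {
    idx <- which(y == cls)
    foldid[idx] <- sample(rep_len(seq_len(nFolds), length(idx)))
  }
  foldid
}

#' Partition labeled pairs into training and testing sets
#'
#' Stratified by label so both sets contain positives. When a network and
#' prediction metaedge are supplied, also builds the training (masked)
#' network with every *testing* positive's edge removed, so that testing
#' labels can never leak into training features.
#'
#' @param pairs data.frame with columns `source`, `target`, `label`.
#' @param testFraction fraction held out for testing (default 0.25).
#' @param seed integer seed.
#' @param hetnet optional [HetNet-class] to mask.
#' @param predictionMetaedge metaedge id of the labeled edges (required when
#'   `hetnet` is given).
#' @return a list of class `"Partition"`: `train`, `test` (disjoint
#'   data.frames whose union is `pairs`), `seed`, and `maskedNetwork`
#'   (`NULL` when no network was supplied).
#' @export
partitionPairs <- function(pairs, testFraction = 0.25, seed = 0,
                           hetnet = NULL, predictionMetaedge = NULL) {
  if (testFraction <= 0 || testFraction >= 1)
    stopf("testFraction must lie strictly between 0 and 1")
  y <- as.integer(pairs$label)
  if (sum(y == 1) < 2)
    stopf("too few positives to stratify the partition")
  testIdx <- withSeed(seed, {
    idx <- integer(0)
    for (cls in unique(y)) {
      clsIdx <- which(y == cls)
      nTest <- floor(testFraction * length(clsIdx) + 0.5)
      nTest <- max(min(nTest, length(clsIdx) - 1), if (cls == 1) 1 else 0)
      idx <- c(idx, sample(clsIdx, nTest))
    }
    sort(idx)
  })
  train <- pairs[-testIdx, , drop = FALSE]
  test <- pairs[testIdx, , drop = FALSE]
  rownames(train) <- rownames(test) <- NULL
  maskedNetwork <- NULL
  if (!is.null(hetnet)) {
    if (is.null(predictionMetaedge))
      stopf("predictionMetaedge is required to build the masked network")
    pos <- test[test$label == 1, , drop = FALSE]
    keys <- mapply(function(s, t) edgeKey(hetnet, s, t, predictionMetaedge),
                   pos$source, pos$target)
    maskedNetwork <- removeEdges(hetnet, keys)
  }
  structure(list(train = train, test = test, seed = seed,
                 testFraction = testFraction, maskedNetwork = maskedNetwork),
            class = "Partition")
}

#' Standardize feature columns to z-scores
#'
#' Centers and scales each column to mean 0 and SD 1. Zero-variance columns
#' are mapped to all-zero with a warning (their coefficient can never be
#' informative). The returned transform is what [predictProbabilities()]
#' applies to new rows, so test rows are always scored with *training*
#' statistics, never their own.
#'
#' @param x numeric matrix (or feature-matrix data.frame; the feature
#'   columns are used).
#' @return a list: `x` (the z-scored matrix), `center`, `scale` (named
#'   numeric vectors; `scale` is 0 for constant columns).
#' @export
standardizeFeatures <- function(x) {
  x <- featuresAsMatrix(x)
  center <- colMeans(x)
  scale <- apply(x, 2, stats::sd)
  if (any(scale == 0))
    warnf("zero-variance feature column(s) mapped to zero: %s",
          paste(colnames(x)[scale == 0], collapse = ", "))
  z <- applyStandardization(list(center = center, scale = scale), x)
  list(x = z, center = center, scale = scale)
}

applyStandardization <- function(transform, x) {
  x <- featuresAsMatrix(x)
  if (!identical(colnames(x), names(transform$center)))
    stopf("feature columns do not match the standardization transform")
  z <- sweep(x, 2, transform$center, "-")
  safeScale <- ifelse(transform$scale == 0, Inf, transform$scale)
  sweep(z, 2, safeScale, "/")
}

featuresAsMatrix <- function(x) {
  if (is.data.frame(x))
    x <- as.matrix(x[, featureColumns(x), drop = FALSE])
  storage.mode(x) <- "double"
  x
}

#' Fit elastic-net regularized logistic regression
#'
#' Fits a binomial glmnet path on standardized features and selects lambda by
#' k-fold cross-validation with the one-standard-error rule: the largest
#' lambda whose mean CV binomial deviance lies within one standard error of
#' the minimum. The final model is refit on all rows at the selected lambda.
#' Folds are stratified by label (with 0.1% prevalence, unstratified folds
#' routinely lack positives).
#'
#' @param x standardized feature matrix (from [standardizeFeatures()]).
#' @param y binary 0/1 labels.
#' @param alpha elastic-net mixing parameter: 0 ridge (default), 1 lasso.
#' @param lambda optional decreasing lambda grid; by default glmnet's
#'   data-driven log-spaced grid of ~100 values from the maximal penalty.
#' @param nFolds number of CV folds (default 10).
#' @param seed integer seed (fold assignment).
#' @param transform optional standardization transform (list with `center`,
#'   `scale`) stored in the fit so that [predictProbabilities()] can score
#'   raw feature rows.
#' @return a [ModelFit-class].
#' @export
fitRegularizedLogistic <- function(x, y, alpha = 0, lambda = NULL,
                                   nFolds = 10, seed = 0, transform = NULL) {
  x <- featuresAsMatrix(x)
  y <- as.integer(y)
  if (nFolds < 2) stopf("nFolds must be at least 2")
  foldid <- withSeed(seed, stratifiedFolds(y, nFolds))
  cvfit <- tryCatch(
    glmnet::cv.glmnet(x, y, family = "binomial", alpha = alpha,
                      lambda = lambda, foldid = foldid,
                      type.measure = "deviance", standardize = FALSE),
    error = function(e) stopf("glmnet failed: %s", conditionMessage(e)))
  sel <- cvfit$lambda.1se
  cf <- as.matrix(stats::coef(cvfit, s = sel))
  beta <- cf[-1, 1]
  names(beta) <- colnames(x)
  if (is.null(transform))
    transform <- list(center = stats::setNames(rep(0, ncol(x)), colnames(x)),
                      scale = stats::setNames(rep(1, ncol(x)), colnames(x)))
  new("ModelFit", alpha = alpha, lambda = sel, intercept = cf[1, 1],
      coefficients = beta,
      center = transform$center, scale = transform$scale,
      cvProfile = data.frame(lambda = cvfit$lambda,
                             meanDeviance = cvfit$cvm,
                             sdDeviance = cvfit$cvsd))
}

#' Coefficient accessors for ModelFit
#'
#' `coef()` returns the standardized coefficients (the fit is on z-scores);
#' `rawCoefficients()` converts back to the raw feature scale by dividing by
#' each column's SD (constant columns get 0), so the two linear predictors
#' are identical: `beta_std = beta_raw * SD(x)`.
#'
#' @param object a [ModelFit-class].
#' @param ... unused.
#' @return named numeric vector.
#' @export
setMethod("coef", "ModelFit", function(object, ...) object@coefficients)

#' @rdname coef-ModelFit-method
#' @param fit a [ModelFit-class].
#' @export
rawCoefficients <- function(fit) {
  ifelse(fit@scale == 0, 0, fit@coefficients / ifelse(fit@scale == 0, 1, fit@scale))
}

setMethod("show", "ModelFit", function(object) {
  cat(sprintf("ModelFit: alpha = %g, lambda = %.4g, %d features (%d nonzero)\n",
              object@alpha, object@lambda, length(object@coefficients),
              sum(object@coefficients != 0)))
})

#' Predicted probabilities from a fitted model
#'
#' Applies the fit's stored standardization to new raw feature rows and
#' returns the inverse-logit of the linear predictor.
#'
#' @param fit a [ModelFit-class].
#' @param x new feature rows (matrix or feature-matrix data.frame) on the
#'   raw scale; columns must match the fit.
#' @return numeric vector of probabilities in (0, 1).
#' @export
predictProbabilities <- function(fit, x) {
  x <- featuresAsMatrix(x)
  if (!identical(colnames(x), names(fit@coefficients)))
    stopf("feature columns do not match the fitted model")
  z <- applyStandardization(list(center = fit@center, scale = fit@scale), x)
  as.vector(stats::plogis(fit@intercept + z %*% fit@coefficients))
}

#' Grid search over elastic-net mixing and damping exponent
#'
#' Repeated stratified k-fold cross-validation of the full pipeline for each
#' (alpha, w) cell. Within every fold the held-out positives' edges are
#' removed from the network before features are recomputed, so masking is
#' honored fold by fold; the reported AUROC is the mean over folds of the
#' held-out pairs' AUROC (with its SD).
#'
#' @param hetnet a [HetNet-class].
#' @param pairs labeled pairs (`source`, `target`, `label`).
#' @param alphaGrid,wGrid numeric grids (non-empty).
#' @param nFolds folds per repeat (default 5).
#' @param nRepeats randomized repartitionings (default 2).
#' @param seed integer seed.
#' @param predictionMetaedge metaedge id being predicted.
#' @param maxLength maximum metapath length (default 3).
#' @param innerFolds folds for the nested lambda selection (default 4).
#' @return data.frame: `alpha`, `w`, `meanAuroc`, `sdAuroc`, `nFolds`.
#' @export
gridSearchHyperparameters <- function(hetnet, pairs, alphaGrid, wGrid,
                                      nFolds = 5, nRepeats = 2, seed = 0,
                                      predictionMetaedge, maxLength = 3,
                                      innerFolds = 4) {
  if (!length(alphaGrid) || !length(wGrid)) stopf("grids must be non-empty")
  y <- as.integer(pairs$label)
  cell <- list()
  for (a in alphaGrid) for (w in wGrid)
    cell[[paste(a, w)]] <- numeric(0)
  withSeed(seed, {
    for (rep_ in seq_len(nRepeats)) {
      foldid <- stratifiedFolds(y, nFolds)
      for (f in seq_len(nFolds)) {
        testIdx <- which(foldid == f)
        pos <- pairs[intersect(testIdx, which(y == 1)), , drop = FALSE]
        keys <- if (nrow(pos)) mapply(function(s, t)
          edgeKey(hetnet, s, t, predictionMetaedge), pos$source, pos$target)
          else character(0)
        foldNet <- removeEdges(hetnet, keys)
        for (w in wGrid) {
          config <- featureConfig(hetnet@metagraph, predictionMetaedge,
                                  w = w, maxLength = maxLength)
          fm <- computeFeatureMatrix(foldNet, pairs, config)
          xTrain <- fm[-testIdx, , drop = FALSE]
          xTest <- fm[testIdx, , drop = FALSE]
          std <- suppressWarnings(standardizeFeatures(xTrain))
          for (a in alphaGrid) {
            innerSeed <- sample.int(.Machine$integer.max, 1)
            # tiny CV folds legitimately hold few positives at desk scale;
            # glmnet warns about them on every inner fit
            fit <- suppressWarnings(fitRegularizedLogistic(
              std$x, y[-testIdx], alpha = a, nFolds = innerFolds,
              seed = innerSeed,
              transform = list(center = std$center, scale = std$scale)))
            p <- predictProbabilities(fit, xTest)
            cell[[paste(a, w)]] <- c(cell[[paste(a, w)]],
                                     auroc(p, y[testIdx]))
          }
        }
      }
    }
  })
  out <- expand.grid(alpha = alphaGrid, w = wGrid, KEEP.OUT.ATTRS = FALSE)
  out$meanAuroc <- NA_real_
  out$sdAuroc <- NA_real_
  for (i in seq_len(nrow(out))) {
    v <- cell[[paste(out$alpha[i], out$w[i])]]
    out$meanAuroc[i] <- mean(v)
    out$sdAuroc[i] <- stats::sd(v)
  }
  out$nFolds <- nFolds * nRepeats
  out
}
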