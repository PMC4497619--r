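simulatedLogisticData <- function(n, beta, intercept = -1, seed = 1) {
  withr::with_seed(seed, {
    x <- matrix(rnorm(n * length(beta)), n,
                dimnames = list(NULL, paste0("f", seq_along(beta))))
    p <- plogis(intercept + x %*% beta)
    list(x = x, y = rbinom(n, 1, p))
  })
}

test_that("partitioning is stratified, label-masking, and seed-stable", {
  # the scale of the study's label set: 698 positives at a 25% holdout
  pairs <- data.frame(source = sprintf("G%04d", 1:3000),
                      target = "D1",
                      label = rep(c(1, 0), c(698, 2302)))
  part <- partitionPairs(pairs, testFraction = 0.25, seed = 4)
  expect_equal(sum(part$test$label), 175)
  expect_equal(nrow(part$test) + nrow(part$train), nrow(pairs))
  expect_equal(nrow(part$test), 175 + 576)
  part2 <- partitionPairs(pairs, testFraction = 0.25, seed = 4)
  expect_identical(part$test, part2$test)
  small <- data.frame(source = sprintf("G%d", 1:100), target = "D1",
                      label = rep(c(1, 0), c(20, 80)))
  p2 <- partitionPairs(small, 0.25, seed = 1)
  expect_equal(nrow(p2$test), 25)
  expect_error(partitionPairs(data.frame(source = "G1", target = "D1",
                                         label = 1), 0.25, 1),
               "too few positives")
})

test_that("the masked training network removes exactly the testing positives' edges", {
  fx <- randomToyNet(51, nPositives = 8)
  part <- partitionPairs(fx$pairs, 0.25, seed = 5, hetnet = fx$hetnet,
                         predictionMetaedge = "DaG")
  eg <- edges(part$maskedNetwork)
  keys <- paste(eg$source, eg$metaedge, eg$target, sep = "|")
  testPos <- part$test[part$test$label == 1, ]
  expect_gt(nrow(testPos), 0)
  for (i in seq_len(nrow(testPos)))
    expect_false(edgeKey(fx$hetnet, testPos$source[i], testPos$target[i],
                         "DaG") %in% keys)
  trainPos <- part$train[part$train$label == 1, ]
  for (i in seq_len(nrow(trainPos)))
    expect_true(edgeKey(fx$hetnet, trainPos$source[i], trainPos$target[i],
                        "DaG") %in% keys)
})

test_that("standardization yields z-scores and reapplies training statistics", {
  set.seed(6)
  x <- matrix(rexp(200), 50, dimnames = list(NULL, paste0("f", 1:4)))
  std <- standardizeFeatures(x)
  expect_lt(max(abs(colMeans(std$x))), 1e-10)
  expect_lt(max(abs(apply(std$x, 2, sd) - 1)), 1e-10)
  xNew <- matrix(rexp(40), 10, dimnames = list(NULL, paste0("f", 1:4)))
  zNew <- hetpath:::applyStandardization(std, xNew)
  expect_equal(zNew, sweep(sweep(xNew, 2, std$center), 2, std$scale, "/"))
  # test rows are scored with training statistics, not their own
  expect_gt(max(abs(colMeans(zNew))), 1e-10)
  xc <- cbind(x, const = 5)
  expect_warning(stdC <- standardizeFeatures(xc), "zero-variance")
  expect_true(all(stdC$x[, "const"] == 0))
})

test_that("lasso on pure-noise features selects the null model", {
  dat <- simulatedLogisticData(2000, rep(0, 8), intercept = -1.5, seed = 7)
  std <- standardizeFeatures(dat$x)
  fit <- fitRegularizedLogistic(std$x, dat$y, alpha = 1, nFolds = 10,
                                seed = 7)
  expect_true(all(coef(fit) == 0))
})

test_that("ridge gives duplicated columns equal coefficients", {
  dat <- simulatedLogisticData(1000, c(1, 0.5), seed = 8)
  x <- cbind(dat$x, dup1 = dat$x[, 1])
  std <- standardizeFeatures(x)
  fit <- fitRegularizedLogistic(std$x, dat$y, alpha = 0, nFolds = 5, seed = 8)
  # equality up to glmnet's coordinate-descent convergence tolerance
  expect_equal(coef(fit)[["f1"]], coef(fit)[["dup1"]], tolerance = 1e-3)
})

test_that("ridge recovers simulated coefficients up to shrinkage", {
  beta <- c(1.2, -0.9, 0.6, -0.5, 0.5, 0, 0, 0.1, -0.1, 0)
  dat <- simulatedLogisticData(5000, beta, seed = 9)
  std <- standardizeFeatures(dat$x)
  fit <- fitRegularizedLogistic(std$x, dat$y, alpha = 0, nFolds = 10, seed = 9)
  est <- coef(fit)
  expect_gt(cor(est, beta), 0.9)
  big <- abs(beta) >= 0.5
  expect_true(all(sign(est[big]) == sign(beta[big])))
})

test_that("the selected lambda obeys the one-standard-error rule", {
  dat <- simulatedLogisticData(800, c(1, -0.5, 0, 0), seed = 10)
  std <- standardizeFeatures(dat$x)
  fit <- fitRegularizedLogistic(std$x, dat$y, alpha = 1, nFolds = 10, seed = 10)
  prof <- fit@cvProfile
  iMin <- which.min(prof$meanDeviance)
  eligible <- prof$lambda[prof$meanDeviance <=
                            prof$meanDeviance[iMin] + prof$sdDeviance[iMin]]
  expect_equal(fit@lambda, max(eligible))
})

test_that("lasso sparsity is monotone along the regularization path", {
  dat <- simulatedLogisticData(600, c(1, -0.8, 0.5, 0, 0, 0), seed = 11)
  std <- standardizeFeatures(dat$x)
  path <- glmnet::glmnet(std$x, dat$y, family = "binomial", alpha = 1,
                         standardize = FALSE)
  nonzero <- colSums(as.matrix(path$beta) != 0)
  # lambda decreases along the path, so nonzero counts must not decrease
  expect_true(all(diff(nonzero) >= 0))
})

test_that("predicted probabilities apply the stored transform consistently", {
  dat <- simulatedLogisticData(500, c(0.8, -0.4, 0.2), seed = 12)
  std <- standardizeFeatures(dat$x)
  fit <- fitRegularizedLogistic(std$x, dat$y, alpha = 0, nFolds = 5, seed = 12,
                                transform = std)
  p <- predictProbabilities(fit, dat$x)
  expect_true(all(p > 0 & p < 1))
  # refit-consistency: same linear predictor as applying coefs to z-scores
  eta <- fit@intercept + std$x %*% coef(fit)
  expect_equal(p, as.vector(plogis(eta)), tolerance = 1e-12)
  # monotonicity in a positively weighted feature
  posFeat <- names(which.max(coef(fit)))
  xUp <- dat$x[1:5, , drop = FALSE]
  xUp[, posFeat] <- xUp[, posFeat] + 1
  expect_true(all(predictProbabilities(fit, xUp) >
                    predictProbabilities(fit, dat$x[1:5, , drop = FALSE])))
  expect_error(predictProbabilities(fit, dat$x[, c(2, 1, 3)]),
               "do not match")
})

test_that("all-zero coefficients predict the constant intercept probability", {
  dat <- simulatedLogisticData(300, rep(0, 4), intercept = -2, seed = 13)
  std <- standardizeFeatures(dat$x)
  fit <- fitRegularizedLogistic(std$x, dat$y, alpha = 1, nFolds = 5, seed = 13,
                                transform = std)
  if (all(coef(fit) == 0)) {
    p <- predictProbabilities(fit, dat$x)
    expect_equal(p, rep(plogis(fit@intercept), length(p)))
  } else {
    succeed("lasso kept a coefficient; constant-probability case not reached")
  }
})

test_that("standardized coefficients equal raw coefficients times column SD", {
  dat <- simulatedLogisticData(700, c(0.9, -0.6, 0.3), seed = 14)
  x <- sweep(dat$x, 2, c(1, 10, 0.1), "*")  # unequal scales
  std <- standardizeFeatures(x)
  fit <- fitRegularizedLogistic(std$x, dat$y, alpha = 0, nFolds = 5, seed = 14,
                                transform = std)
  expect_equal(rawCoefficients(fit) * std$scale, coef(fit))
  # and against an unregularized glm: beta_std ~= beta_raw * sd(x)
  g <- glm(dat$y ~ x, family = binomial)
  gz <- glm(dat$y ~ std$x, family = binomial)
  expect_equal(unname(coef(g)[-1] * std$scale), unname(coef(gz)[-1]),
               tolerance = 1e-6)
})

test_that("grid search is deterministic and reduces to repeated CV for one cell", {
  fx <- randomToyNet(55, nGene = 10, nDisease = 3, nPositives = 6)
  tab <- gridSearchHyperparameters(fx$hetnet, fx$pairs, alphaGrid = 0,
                                   wGrid = 0.4, nFolds = 3, nRepeats = 2,
                                   seed = 15, predictionMetaedge = "DaG")
  expect_equal(nrow(tab), 1)
  expect_equal(tab$nFolds, 6)
  expect_true(is.finite(tab$meanAuroc) && tab$meanAuroc >= 0 &&
                tab$meanAuroc <= 1)
  tab2 <- gridSearchHyperparameters(fx$hetnet, fx$pairs, alphaGrid = 0,
                                    wGrid = 0.4, nFolds = 3, nRepeats = 2,
                                    seed = 15, predictionMetaedge = "DaG")
  expect_identical(tab, tab2)
})

test_that("damping helps when hub-routed membership noise is planted", {
  # signal: shared membership in small pathways; noise: one promiscuous
  # pathway hub joining most genes, creating uninformative paths that the
  # plain path count cannot tell apart from signal
  planted <- plantedSignalNet(56, nGene = 24, nDisease = 4, nPathway = 6,
                              effectSize = 20, nPositives = 20)
  h <- planted$hetnet
  nd <- rbind(nodes(h),
              data.frame(identifier = "Pw999", metanode = "Pathway",
                         name = "Pw999"))
  genes <- nd$identifier[nd$metanode == "Gene"]
  hubEdges <- data.frame(source = genes[1:20], metaedge = "GmPw",
                         target = "Pw999", stringsAsFactors = FALSE)
  eg <- rbind(edges(h)[, c("source", "metaedge", "target")], hubEdges)
  hNoisy <- hetNet(metaGraph(h), nd, eg)
  tab <- gridSearchHyperparameters(hNoisy, planted$pairs, alphaGrid = 0,
                                   wGrid = c(0, 0.6), nFolds = 3,
                                   nRepeats = 1, seed = 16,
                                   predictionMetaedge = "DaG")
  expect_gte(tab$meanAuroc[tab$w == 0.6], tab$meanAuroc[tab$w == 0])
})
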