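test_that("AUROC handles separation, chance, ties and matches Mann-Whitney", {
  expect_equal(auroc(c(5, 4, 3, 2, 1), c(1, 1, 0, 0, 0)), 1.0)
  expect_equal(auroc(c(1, 2, 3, 4), c(1, 1, 0, 0)), 0.0)
  withr::with_seed(61, {
    scores <- rnorm(4000)
    labels <- rbinom(4000, 1, 0.3)
    expect_equal(auroc(scores, labels), 0.5, tolerance = 0.05)
    # rank formulation equals explicit pair counting with half ties
    s <- sample(1:8, 60, replace = TRUE)  # heavy ties
    y <- rbinom(60, 1, 0.4)
    pos <- s[y == 1]; neg <- s[y == 0]
    pairwise <- mean(outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b)))
    expect_equal(auroc(s, y), pairwise)
    # and the Mann-Whitney U statistic normalization
    u <- wilcox.test(pos, neg, exact = FALSE)$statistic
    expect_equal(auroc(s, y), unname(u) / (length(pos) * length(neg)))
  })
  expect_error(auroc(1:3, c(1, 1, 1)), "both classes")
})

test_that("AUROC is invariant under strictly monotone score transforms", {
  withr::with_seed(62, {
    scores <- rnorm(300)
    labels <- rbinom(300, 1, 0.2)
    a <- auroc(scores, labels)
    expect_equal(auroc(exp(scores), labels), a)
    expect_equal(auroc(qlogis(plogis(scores * 3 + 1)), labels), a)
  })
})

test_that("precision at recall follows the threshold-scan definition", {
  # all positives ranked first: precision 1 at every recall level below the
  # boundary (recall 1 itself thresholds at the minimum, giving prevalence)
  s <- 10:1
  y <- rep(c(1, 0), c(4, 6))
  for (r in c(0.25, 0.5, 0.99))
    expect_equal(precisionAtRecall(s, y, r), 1.0)
  expect_equal(precisionAtRecall(s, y, 1), 0.4)
  # recall 1 at the lowest threshold: precision equals prevalence
  withr::with_seed(63, {
    scores <- rnorm(500)
    labels <- rbinom(500, 1, 0.1)
    expect_equal(precisionAtRecall(scores, labels, 1), mean(labels))
    # brute-force scan over every threshold
    bruteAtRecall <- function(lvl) {
      ths <- sort(unique(scores), decreasing = TRUE)
      for (th in ths) {
        sel <- scores >= th
        if (sum(labels[sel]) / sum(labels) >= lvl)
          return(mean(labels[sel]))
      }
    }
    for (lvl in c(0.1, 0.3, 0.7))
      expect_equal(precisionAtRecall(scores, labels, lvl), bruteAtRecall(lvl))
  })
  expect_error(precisionAtRecall(s, y, 0), "recallLevel")
})

test_that("fold enrichment is precision over prevalence", {
  expect_equal(foldEnrichment(0.3, 0.3), 1.0)
  expect_equal(foldEnrichment(0, 0.1), 0)
  expect_error(foldEnrichment(0.5, 0), "positive")
  # the arithmetic at the study's scale: 16.7% precision against a 0.13%
  # prevalence is a ~132-fold enrichment
  expect_equal(foldEnrichment(0.167, 698 / (698 + 551823)), 132, tolerance = 0.01)
})

test_that("the exponential CROC transform is normalized and magnifies early FPR", {
  for (a in c(0.5, 7, 460)) {
    expect_equal(crocTransform(0, a), 0)
    expect_equal(crocTransform(1, a), 1)
  }
  expect_equal(crocTransform(0.01, 460), 0.99, tolerance = 1e-3)
  # the magnification solving f(0.01) = 0.99 exactly is 100*log(100)
  aStar <- 100 * log(100)
  expect_equal(crocTransform(0.01, aStar), 0.99, tolerance = 1e-9)
  # small-magnification limit: identity
  x <- seq(0, 1, 0.05)
  expect_equal(crocTransform(x, 1e-8), x, tolerance = 1e-6)
  expect_true(all(diff(crocTransform(x, 460)) >= 0))
})

test_that("CROC area rewards early retrieval and penalizes its absence", {
  # Reweighting an increasing TPR curve toward low FPR can only lower the
  # area, so CROC area <= AUROC pointwise; the discriminating property is
  # relative: of two classifiers with equal AUROC, the one concentrating its
  # hits at the top of the ranking gets the larger CROC area.
  withr::with_seed(64, {
    n <- 1000
    # both have AUROC exactly 0.5: half the hits at the very top (early
    # retriever) versus all hits mid-ranking
    yEarly <- c(rep(1, 25), rep(0, 950), rep(1, 25))
    yMid <- c(rep(0, 475), rep(1, 50), rep(0, 475))
    sRank <- n:1  # scores by rank position
    expect_equal(auroc(sRank, yEarly), 0.5)
    expect_equal(auroc(sRank, yMid), 0.5)
    expect_gt(crocArea(sRank, yEarly, 460), crocArea(sRank, yMid, 460))
    # and the pointwise bound, with equality for a perfect classifier
    s <- rnorm(400); y <- rbinom(400, 1, 0.2)
    expect_lte(crocArea(s, y, 460), auroc(s, y) + 1e-12)
    expect_equal(crocArea(y * 10 + rnorm(400), y, 460), 1, tolerance = 0.05)
  })
})

test_that("the unpaired DeLong test behaves at the null and under separation", {
  withr::with_seed(65, {
    s <- rnorm(200); y <- rbinom(200, 1, 0.4)
    same <- delongTestUnpaired(s, y, s, y)
    expect_equal(same$pValue, 0.5)
    expect_equal(same$z, 0)
    # A perfectly separated, B random
    yA <- rep(c(1, 0), each = 250)
    sA <- c(rnorm(250, 5), rnorm(250, 0))
    sB <- rnorm(500); yB <- rbinom(500, 1, 0.5)
    res <- delongTestUnpaired(sA, yA, sB, yB)
    expect_lt(res$pValue, 0.001)
    expect_gt(delongTestUnpaired(sB, yB, sA, yA)$pValue, 0.999)
  })
})

test_that("DeLong AUROC variance agrees with the bootstrap", {
  withr::with_seed(66, {
    scores <- rnorm(200) + 0.8 * (y <- rbinom(200, 1, 0.35))
    v <- hetpath:::delongVariance(scores, y)
    boots <- replicate(1500, {
      idx <- sample(200, replace = TRUE)
      if (length(unique(y[idx])) < 2) NA else auroc(scores[idx], y[idx])
    })
    expect_equal(v$var, var(boots, na.rm = TRUE), tolerance = 0.2)
  })
})

test_that("DeLong results match the reference implementation in pROC", {
  skip_if_not_installed("pROC")
  withr::with_seed(67, {
    yA <- rbinom(300, 1, 0.3); sA <- rnorm(300) + yA
    yB <- rbinom(300, 1, 0.3); sB <- rnorm(300) + 0.4 * yB
    ours <- delongTestUnpaired(sA, yA, sB, yB)
    ref <- pROC::roc.test(
      pROC::roc(yA, sA, quiet = TRUE, direction = "<"),
      pROC::roc(yB, sB, quiet = TRUE, direction = "<"),
      method = "delong", paired = FALSE, alternative = "greater")
    # identical statistic; pROC refers it to a Welch t instead of the
    # asymptotic normal, so compare z exactly and p under the same reference
    expect_equal(ours$z, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(ours$pValue,
                 pnorm(unname(ref$statistic), lower.tail = FALSE))
    expect_equal(ours$pValue, unname(ref$p.value), tolerance = 0.02)
    expect_equal(ours$aucA, unname(as.numeric(ref$estimate[1])))
  })
})

test_that("feature performance separates planted signal from random features", {
  planted <- plantedSignalNet(68, nGene = 24, nDisease = 4, nPathway = 6,
                              effectSize = 20, nPositives = 20)
  config <- featureConfig(metaGraph(planted$hetnet), "DaG")
  fm <- computeFeatureMatrix(planted$hetnet, planted$pairs, config)
  withr::with_seed(68, fm$DWPC_random <- rnorm(nrow(fm)))
  perf <- featurePerformance(fm, perGroup = "target")
  expect_setequal(perf$global$feature, c(config$featureNames, "DWPC_random"))
  aurocOf <- function(f) perf$global$auroc[perf$global$feature == f]
  expect_gt(aurocOf("DWPC_GmPwmGaD"), 0.6)
  expect_equal(aurocOf("DWPC_random"), 0.5, tolerance = 0.15)
  # per-disease AUROCs average near the global value for the planted feature
  byG <- perf$byGroup[perf$byGroup$feature == "DWPC_GmPwmGaD", ]
  expect_gt(nrow(byG), 0)
  expect_equal(mean(byG$auroc), aurocOf("DWPC_GmPwmGaD"), tolerance = 0.15)
})

test_that("gene-set subsampling degrades the affected feature toward chance", {
  planted <- plantedSignalNet(69, nGene = 20, nDisease = 4, nPathway = 5,
                              effectSize = 20, nPositives = 16)
  h <- planted$hetnet
  tab <- subsampleGeneSet(h, "Pathway", scheme = "node",
                          percentages = c(0, 50, 100), repetitions = 3,
                          seed = 70, pairs = planted$pairs,
                          predictionMetaedge = "DaG", w = 0.4)
  expect_equal(nrow(tab), 9)
  # 0% masking reproduces the unmasked feature AUROC
  config <- featureConfig(metaGraph(h), "DaG")
  fm <- computeFeatureMatrix(h, planted$pairs, config)
  base <- auroc(fm$DWPC_GmPwmGaD, fm$label)
  expect_equal(unique(tab$auroc[tab$percentage == 0]), base)
  # 100% node masking leaves no paths: constant feature, AUROC 0.5
  expect_equal(unique(tab$auroc[tab$percentage == 100]), 0.5)
  # mean AUROC non-increasing in masking percentage
  means <- tapply(tab$auroc, tab$percentage, mean)
  expect_true(all(diff(means) <= 0.05))
  # edge masking at 100% behaves the same
  tabE <- subsampleGeneSet(h, "Pathway", scheme = "edge", percentages = 100,
                           repetitions = 1, seed = 71, pairs = planted$pairs,
                           predictionMetaedge = "DaG")
  expect_equal(tabE$auroc, 0.5)
})
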