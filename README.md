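# hetpath

Edge prediction on heterogeneous networks (hetnets) — typed graphs whose
nodes and edges carry user-defined types — with metapath-based topology
features. The motivating application is prioritizing gene–disease
associations: given a network that integrates GWAS-derived associations,
protein interactions, tissue-specific expression, disease localization and
gene-set memberships, predict the probability that each gene is associated
with each disease, so that future association studies can spend their
power where biology concentrates it.

## The core statistic

The topology joining a candidate pair $(s, t)$ is summarized per metapath
$m$ (a typed sequence of edge types, e.g. `GeTlD` =
Gene–expression–Tissue–localization–Disease). The primary metric is the
**degree-weighted path count**: every simple path of type $m$ from $s$ to
$t$ receives a path-degree product

$$PDP(path) = \prod_{d \in D_{path}} d^{-w}, \qquad
DWPC_m(s,t) = \sum_{path \in Paths_m(s,t)} PDP(path),$$

where $D_{path}$ holds the metaedge-specific degrees of both endpoints of
every edge on the path and $w \ge 0$ (default 0.4) damps hub-routed paths;
$w = 0$ recovers the raw path count. On the bundled 18-metanode /
19-metaedge gene–disease schema this yields 22 DWPC features (metapaths of
length ≤ 3) plus two association-degree counts (gene pleiotropy, disease
polygenicity) — 24 features per pair, always computed with the pair's own
association edge masked so labels cannot leak into features. A
regularized logistic model (ridge by default, cross-validated penalty with
the one-standard-error rule) converts features into association
probabilities, and degree-preserving XSwap permutations provide the null
that separates edge-specific signal from degree effects. Evaluation
utilities include AUROC, precision-at-recall, fold enrichment,
concentrated ROC (early retrieval) and unpaired DeLong tests.

A synthetic-data module generates schema-conforming random hetnets with
controllable degree heterogeneity and plantable metapath signal, so the
entire pipeline is testable at desk scale.

## Worked example

Simulate a network in which genes sharing pathway membership with a
disease's known genes are far likelier to be associated (`GmPwmGaD`
signal), hold out 25% of pairs, and fit the ridge model on the masked
training network:

```r
library(hetpath)
mg <- toyMetagraph()
net <- generateHetNet(
  mg,
  nodeCounts = c(Gene = 84, Disease = 6, Tissue = 4, Pathway = 10),
  edgeParams = list(GeT = list(density = 0.15), DlT = list(density = 0.4),
                    GiG = list(density = 0.05, distribution = "powerlaw"),
                    GmPw = list(density = 0.12)),
  seed = 101)
planted <- plantAssociations(net, "GmPwmGaD", effectSize = 12,
                             nPositives = 40, seed = 102)
planted$hetnet
#> HetNet with 104 nodes and 375 edges
#>   DaG          40
#>   DlT          10
#>   GeT          50
#>   GiG          174
#>   GmPw         101

part <- partitionPairs(planted$pairs, 0.25, seed = 1,
                       hetnet = planted$hetnet, predictionMetaedge = "DaG")
config <- featureConfig(mg, "DaG", w = 0.4)
fm <- computeFeatureMatrix(part$maskedNetwork,
                           rbind(part$train, part$test), config)
isTest <- seq_len(nrow(fm)) > nrow(part$train)
std <- standardizeFeatures(fm[!isTest, ])
fit <- fitRegularizedLogistic(std$x, fm$label[!isTest], alpha = 0,
                              seed = 1, transform = std)
round(sort(coef(fit), decreasing = TRUE), 3)
#>      DWPC_GmPwmGaD PC_GaD_any_disease       DWPC_GaDlTlD         DWPC_GeTlD
#>              0.764              0.077              0.038              0.020
#>       DWPC_GeTeGaD         DWPC_GiGaD       DWPC_GaDaGaD       DWPC_GiGeTlD
#>             -0.047             -0.095             -0.106             -0.113
#>    PC_DaG_any_gene       DWPC_GiGiGaD
#>             -0.162             -0.167

p <- predictProbabilities(fit, fm[isTest, ])
auroc(p, fm$label[isTest])
#> [1] 0.9447005
precisionAtRecall(p, fm$label[isTest], 0.5)
#> [1] 0.7142857
```

The standardized coefficients identify the planted mechanism: the
set-traversing `DWPC_GmPwmGaD` feature dominates (0.76), exactly the
metapath the signal was planted along. Held-out pairs are ranked with
AUROC 0.94, and at 50% recall, 71% of predicted positives are true —
against a 7.9% prevalence, a 9-fold enrichment. Permuting the network
(`permuteNetwork()`, which preserves every metaedge-specific degree)
collapses this feature's discrimination toward chance while leaving
pure-degree features untouched, confirming the signal is edge-specific.

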