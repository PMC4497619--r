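Package: hetpath
Title: Heterogeneous Network Edge Prediction with Metapath Features
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for edge prediction on heterogeneous networks (hetnets):
    typed networks whose nodes and edges are annotated with user-defined
    types. Provides a metagraph schema model, metapath enumeration,
    degree-weighted path count (DWPC) and related metapath feature metrics,
    degree-preserving XSwap permutation null models, regularized logistic
    regression for scoring candidate edges, and early-retrieval evaluation
    (concentrated ROC, unpaired DeLong tests). Includes a synthetic hetnet
    generator with plantable metapath signal so the full pipeline can be
    exercised and validated at small scale. The bundled schema and default
    parameters target gene-disease association prioritization from GWAS
    training labels.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    glmnet,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'metagraph.R'
    'hetnet.R'
    'metapath.R'
    'features.R'
    'modeling.R'
    'evaluation.R'
    'hetpath-package.R'
    'permutation.R'
    'synthetic.R'
    'utils.R'
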