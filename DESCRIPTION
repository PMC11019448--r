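Package: CLixTools
Title: Corticolimbic Index Scoring and Heterogeneity Analysis for
    Alzheimer Disease Neuropathology
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantifies the corticolimbic distribution of neurofibrillary
    tangles in neuropathologically diagnosed Alzheimer disease as a
    continuous 0-40 corticolimbic index (CLix) computed from reference
    percentiles of thioflavin-S tangle counts in posterior hippocampus
    (CA1, subiculum) and association cortices (superior temporal, inferior
    parietal, middle frontal), and bins the index into hippocampal
    sparing, typical, and limbic predominant subtypes. Provides cohort
    containers built on SummarizedExperiment, a brain-bank style exclusion
    cascade, extreme-phenotype subgroup selection, a latent-trait
    synthetic cohort simulator with copula-coupled covariates, and the
    accompanying analysis layer: Spearman and partial Spearman rank
    correlation, Kruskal-Wallis, Wilcoxon rank sum and Fisher exact
    tests, MMSE decline slopes, and random forest permutation variable
    importance (%IncMSE).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    randomForest,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
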