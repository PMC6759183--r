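Package: growthnet
Title: Function-Valued Growth Traits, QTL Mapping, and Co-Expression
    Networks for Recombinant Inbred Line Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An integrated pipeline for dissecting the genetic architecture
    of plant growth from longitudinal field phenotypes and bulk RNA-seq in a
    biparental recombinant inbred line (RIL) population. Fits a three-level
    hierarchical Bayesian logistic growth model by Metropolis-Hastings MCMC
    to extract function-valued traits (growth rate, asymptotic height,
    inflection point, duration) on a thermal-time scale; estimates variance
    components, broad-sense heritability, BLUPs, and plasticity tests with
    mixed models; performs Haley-Knott and composite interval mapping with
    permutation thresholds, iterative multi-QTL model search, LOD-drop and
    Bayesian support intervals; builds trait-seeded mutual-rank co-expression
    networks with permutation significance and signed-hybrid eigengene
    modules; and integrates layers through enrichment, colocalization
    permutation tests, cis/trans eQTL classification, and predictive model
    comparison. A synthetic-study generator with known ground truth supports
    end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    edgeR,
    generics,
    ggplot2,
    jsonlite,
    lme4,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
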