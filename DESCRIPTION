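Package: cgmoa
Title: Bioprocess Target Prediction from Chemical-Genetic Interaction Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Predicts the biological processes (or protein complexes) perturbed
    by chemical compounds by comparing chemical-genetic interaction profiles
    against a compendium of genetic interaction profiles. Compound-gene
    similarity scores are aggregated into per-bioprocess scores, assessed
    against three empirical nulls (solvent controls, resampled profiles, and
    within-profile gene-label permutation), combined conservatively, and
    converted into per-profile false discovery rate estimates. Includes
    enrichment-based baseline predictors, a simulation-based evaluation suite
    (precision-recall, gold-standard rank significance, per-term AUPR), an
    importance-score interpretation layer, and generators for fully synthetic
    screens with planted compound-to-process signal.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml,
    jsonlite
biocViews: Software, SystemsBiology, NetworkInference, GeneSetEnrichment
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
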