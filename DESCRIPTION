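Package: methconcord
Title: Cross-Tissue DNA Methylation Concordance Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantifies how well peripheral tissues (blood, saliva, buccal)
    serve as surrogates for brain DNA methylation within individuals.
    Implements probe-level quality control for methylation arrays
    (detection p-value filtering, an iterative greedy-cut removal of
    unreliable probes and samples, annotation-based exclusion rules, and
    SNP-probe sample-identity verification), two complementary
    cross-tissue correlation frameworks (across-subject Pearson
    correlation of tissue-averaged methylation profiles and per-CpG
    within-subject Spearman correlation with exact permutation p-values
    at small sample sizes), an interpercentile-range classifier of
    variable CpGs, a covariance-corrected test for comparing dependent
    overlapping correlations, stratification of concordance by genomic
    context, regulatory features, mQTL status and gene sets, classical
    multidimensional scaling of samples with a distance-versus-correlation
    regression, and reference-based cell-type composition estimation and
    adjustment. A synthetic multi-tissue cohort generator with known
    latent structure makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
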