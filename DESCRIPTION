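Package: meqtlmr
Title: Cis-meQTL Mapping, Pleiotropy Screening and Mendelian Randomization
    for Exposure-Associated DNA Methylation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for studying the genetic regulation of
    exposure-associated DNA methylation in admixed cohorts: supervised
    genotype-based global ancestry assignment (LD pruning, reference-projected
    PCA, admixture-proportion EM, KNN classification), two-stage epigenome-wide
    association modelling with control-probe and residual principal components
    and reference-based cell-type deconvolution, fixed-effects meta-analysis
    across array cohorts, cis-meQTL mapping with Benjamini-Hochberg FDR control
    and LD clumping into index meQTLs, pleiotropy screening (PheWAS-style
    catalog lookup and Fisher-exact trait enrichment), and two-sample Mendelian
    randomization (inverse-variance weighted, weighted median, and a
    residual-sum-and-outlier pleiotropy test). A synthetic-data generator with
    known ground truth (Balding-Nichols population structure, block LD,
    planted cis effects, exposure effects, and causal paths) makes every stage
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    pracma,
    jsonlite,
    vcfR,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    metafor,
    withr,
    cluster
Config/testthat/edition: 3
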