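Package: btwas
Title: Whole-Blood Transcriptome-Wide Association Analysis of a Quantitative Trait
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested, reusable pipeline for two-cohort transcriptome-wide
    association analysis of a quantitative phenotype (body mass index) in
    whole-blood microarray data: per-transcript covariate-adjusted linear
    regression, sample-size-weighted z-score meta-analysis with
    Benjamini-Hochberg false discovery rate control, probe-to-gene collapsing
    with effect-direction classification, direction-stratified gene-set
    over-representation analysis with a permutation null, and a
    Jaccard-threshold pathway-overlap graph. Includes a synthetic-data
    generator that emulates the statistical structure of paired
    population-based cohorts (covariates, planted signed effects, a
    reticulocyte-like confounding factor, detection p-values) so that every
    stage is testable with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    data.table,
    limma,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    fgsea,
    withr
Config/testthat/edition: 3
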