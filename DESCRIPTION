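Package: pubmeth
Title: Paired Sex-Stratified Differential Methylation Analysis Across Puberty
Version: 0.1.0
Authors@R: person("COAST", "Methylation Pipeline Maintainers", role = c("aut", "cre"),
    email = "maintainers@example.org")
Description: A tested, reusable pipeline for pre/post-puberty DNA methylation
    analysis on Illumina 450K-style beta-value matrices: probe quality control
    and filtering, paired sex-stratified differential methylation with
    empirical-Bayes variance moderation, nearest-TSS gene assignment,
    permutation testing for enrichment of predicted estrogen-responsive genes
    with exact hypergeometric oracles, correlation-module detection in
    post-puberty expression, an unsupervised hierarchical-clustering puberty
    classifier, and cell-composition / ancestry confound checks. Ships a
    synthetic-cohort generator with ground truth so every stage is testable
    without access to protected cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    limma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
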