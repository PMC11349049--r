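Package: cd8basket
Title: Translational and Statistical Analyses for a CD8-Stratified Basket Trial
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested, reusable pipeline for the translational and statistical
    analyses of a CD8-stratified immunotherapy basket trial: Bayesian
    beta-binomial credible intervals for response and disease-control rates,
    CD8-conversion analysis with logistic association testing, multiplex
    immunofluorescence cell phenotyping via exact one-dimensional k-means
    thresholding, layer-aware differential comparison rules across omics
    matrices (RNA, serum proteomics, mass and flow cytometry, imaging),
    principal-curve pseudotime with GLM trajectory-association testing,
    TCR repertoire diversity and clone sharing, and ctDNA molecular response
    classification. Seeded synthetic-data generators emulate every input
    layer with known ground truth so each stage is recovery-testable without
    patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    limma
Suggests:
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
RoxygenNote: 7.3.3
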