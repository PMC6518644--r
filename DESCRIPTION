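Package: nmropls
Title: OPLS-DA Chemometrics for 1H NMR Serum Metabolomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: End-to-end chemometrics for one-dimensional 1H NMR serum
    metabolomics outcome studies: simulation of CPMG-like serum spectra with
    group- and time-structured metabolite concentrations, spectral bucketing
    with solvent/infusion region exclusion, probabilistic quotient
    normalization, auto-scaling, PCA outlier screening, orthogonal
    projections to latent structures discriminant analysis (OPLS-DA) with
    cross-validated Q2Y and permutation validation, multilevel
    (within-subject) paired models for repeated sampling, and univariate
    screening with Bonferroni and Benjamini-Hochberg correction, relative
    quantification of time trends, and ROC evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    pracma
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
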