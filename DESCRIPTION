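Package: quadindex
Title: Quadratic and Linear Selection Indices for Multi-Trait Genomic Breeding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for multi-trait selection-index breeding with phenotypic and
    genomic information. Implements the Smith-Hazel linear phenotypic selection
    index (LPSI), the linear genomic selection index (LGSI), and their quadratic
    extensions (QPSI, QGSI) that add squared and cross-product trait terms to
    the net genetic merit. Provides MANOVA-based estimation of phenotypic,
    genotypic and genomic covariance matrices; genomic prediction by multi-trait
    GBLUP on standardized markers and by a Bayesian multi-trait Gaussian-kernel
    (RKHS) model; closed-form index coefficients, moments, selection response,
    per-trait expected gains, prediction error and accuracy under truncation
    selection with seeded Monte-Carlo oracles; a recurrent-selection breeding
    cycle simulator with pleiotropic QTL calibrated to target genetic
    correlations; and univariate and multivariate normality tests (Shapiro-Wilk,
    Mardia, Henze-Zirkler) for the distributional assumptions of index theory.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    vcfR
Config/testthat/edition: 3
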