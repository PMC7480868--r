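Package: sweepwave
Title: Wavelet-Based Functional Regression for Detecting Selective Sweeps
    and Adaptive Introgression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Detects and characterizes positive selection from phased
    haplotype data. Spatial distributions of haplotype summary statistics
    (mean pairwise difference, H1, H12, H2/H1, top haplotype frequencies,
    and moments of pairwise r^2) computed in overlapping SNP windows are
    represented by orthonormal discrete wavelet coefficients and used as
    covariates in penalized functional regression: an elastic-net
    multinomial model classifies genomic regions as neutral, selective
    sweep, or adaptive introgression, and a multi-response elastic-net
    linear model predicts the selection coefficient, the initial
    beneficial-allele frequency, and the onset time of selection. Includes
    window-layout arithmetic, a sliding genome-scan driver, readers for
    phased VCF and ms-style haplotype text, and seeded synthetic-data
    generators for testing the statistical machinery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
Imports:
    glmnet,
    jsonlite,
    stats,
    utils,
    graphics,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
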