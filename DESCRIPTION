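Package: dhpredict
Title: Multi-Trait Genomic Prediction for Maize Doubled-Haploid Breeding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis toolkit for genomic prediction in maize
    doubled-haploid (DH) breeding programs. Provides a biparental DH and
    haploid population simulator (Haldane meiosis, recurrent-selfing lines,
    multi-trait phenotypes under a Kronecker genetic covariance), SNP quality
    control and VanRaden genomic relationship matrices, parental-origin
    encoding with recombination counting, univariate genomic prediction
    (spectral REML GBLUP and a BayesB Gibbs sampler), Bayesian multi-trait
    mixed models with diagonal, unstructured and factor-analytic covariance
    structures fitted by Gibbs sampling with missing-data augmentation, a
    high-dimensional factor model for trait-assisted prediction, CV2-style
    cross-validation with genetic-accuracy estimation and the corrected
    resampled t-test, and deterministic selection-response calculators for
    comparing direct selection of DH lines with indirect selection on their
    haploid progenitors.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    lme4,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    ggplot2,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
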