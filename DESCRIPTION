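Package: multitrans
Title: Multiple-Testing Correction for Genome-Wide Association Studies
    with Linear Mixed Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Estimates per-marker significance thresholds that control the
    family-wise error rate of genome-wide association studies performed with
    linear mixed models. Null association statistics are sampled from a
    multivariate normal distribution whose covariance is the correlation of
    genotypes transformed by the inverse square root of the fitted phenotypic
    covariance, using a sliding-window conditional Gaussian sampler.  Also
    provides the parametric-bootstrap gold standard, a naive permutation
    baseline, REML/ML variance-component estimation by spectral
    decomposition, kinship estimation, genotype file handling, and a
    synthetic genotype/phenotype generator with population structure and
    local linkage disequilibrium.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
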