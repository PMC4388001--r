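Package: coansel
Title: Coancestry-Aware BLUP Selection Simulations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Forward-in-time simulation of truncation selection driven by best
    linear unbiased prediction (BLUP) under four relationship matrices: the
    pedigree-based additive relationship, identity-by-state (IBS) molecular
    coancestry, a runs-of-homozygosity (ROH) segment-based coancestry, and the
    VanRaden allele-frequency-corrected genomic relationship. Includes a
    neutral mutation-drift-recombination genome simulator for building base
    populations, a quantitative-trait module, Monte-Carlo EM REML variance
    estimation, an exact mixed-model-equation solver, and per-generation
    tracking of genetic gain, all four coancestries, inbreeding and observed
    heterozygosity, so that pedigree-based and genomic BLUP can be compared in
    terms of gain and diversity maintained.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    readr,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
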