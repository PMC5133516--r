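Package: hdscan
Title: Homozygosity Disequilibrium Scanning and Association Testing
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Estimates per-individual homozygosity intensity along chromosomes
    with a double-weight local polynomial model (a cubic kernel weight over
    physical distance combined with a minor-allele-frequency locus weight that
    down-weights rare-variant sites), calls sizable regions of homozygosity
    disequilibrium, tests regions for association with quantitative and binary
    traits and with gene expression using pedigree-clustered generalized
    estimating equations with robust standard errors and false discovery rate
    control, and provides a pedigree gene-dropping simulator with logistic
    trait-dependent implantation of homozygous tracts for type-I-error and
    power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    optparse,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    sandwich,
    lmtest
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
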