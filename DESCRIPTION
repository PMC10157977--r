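Package: rohdep
Title: Runs of Homozygosity, Genomic Inbreeding and Inbreeding-Depression
    Mapping
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for genome-wide assessment and mapping of inbreeding
    depression from SNP array data with repeated phenotype records. Calls
    runs of homozygosity (ROH) under explicit length, SNP-count, density,
    heterozygote and gap constraints; computes excess-homozygosity (F_SNP)
    and ROH-based (F_ROH) inbreeding coefficients including ROH
    length-class decompositions; fits repeated-records animal models with
    a genomic relationship matrix and a permanent-environment term by
    average-information REML to estimate inbreeding depression; scans the
    genome SNP-by-SNP for homozygosity (ROH-state) effects with a
    proportion-based false discovery rate; and includes a gene-dropping
    simulator with tracked identity-by-descent segments so every stage
    can be validated against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    MASS,
    jsonlite,
    yaml,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
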