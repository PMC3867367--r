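Package: tillpool
Title: Rare-Allele SNP Discovery in Deeply Pooled Amplicon Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for TILLING-by-sequencing of deeply pooled
    PCR amplicons from mutagenised plant populations. Provides exact
    pool allele-frequency arithmetic for equimolar pools of polyploid
    individuals, per-site coverage/frequency statistics with the Shenkin
    information-content variability score, frequency-threshold SNP
    calling, cross-pool Venn classification of calls, identification of
    putatively EMS-induced G/C-to-A/T transitions inside the predicted
    pool-frequency window, exon/intron and codon-level effect annotation,
    mutation-density estimation, and a fully seeded synthetic-data
    generator that emulates the population, pooling, coverage and error
    structure of such studies so that every stage is testable without
    external sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    stringr,
    readr,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    stats,
    utils,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
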