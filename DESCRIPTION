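Package: varconcord
Title: Multi-Caller Variant Concordance, Homozygosity and Copy Number
    Analysis for Resequenced Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Integrates and evaluates variant calls for a single deeply
    resequenced diploid genome. Provides multi-caller SNP consensus and Venn
    partition bookkeeping, SNP-array versus sequencing genotype concordance
    with detection-rate and error-rate estimators, sliding-window run-of-
    homozygosity (ROH) detection, identity-by-descent (IBD) based false
    positive rate estimation, minimum-allele-percentage diagnostics and
    post-hoc heterozygote filtering, indel post-filtering and functional
    characterization, region density enrichment statistics, read-depth copy
    number variant (CNV) calling with cross-platform comparison and
    permutation gene enrichment, Wright's inbreeding coefficient from a
    pedigree, and a synthetic diploid genome generator with planted truth so
    that every pipeline stage is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    IRanges,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    S4Vectors,
    tibble,
    tidyr,
    utils,
    vcfR,
    withr,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
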