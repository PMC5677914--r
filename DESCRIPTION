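Package: pgxcohort
Title: Pharmacogenetic Star-Allele Calling, CYP2D6 Copy Number and
    Actionability for Sequenced Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to extract clinical pharmacogenetics from cohort
    genotype data across sequencing and targeted-genotyping platforms: a
    curated 67-locus/19-gene panel model, VCF and wide-TSV genotype
    readers with quality accounting, unphased star-allele diplotype
    inference with explicit ambiguity handling, CYP2D6 copy-number
    classification from windowed relative coverage with allelic
    read-ratio phasing of duplications, activity-score metabolizer
    phenotyping and guideline-based actionability categories, and
    cross-platform concordance reports. Ships a fully specified synthetic
    cohort generator (ground-truth manifests, platform-realistic VCF/TSV
    call sets, coverage profiles) so every pipeline stage has a recovery
    test without controlled-access data.
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
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    vcfR,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
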