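Package: indelLD
Title: Linkage Disequilibrium and Imputation of Short Insertion-Deletion Variants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Characterizes linkage disequilibrium between short (< 50 bp)
    insertion-deletion polymorphisms (indels) and SNPs from phased diploid
    panels, and evaluates how well indel genotypes can be imputed from
    nearby SNPs.  Provides pairwise haplotype r-squared within configurable
    windows, distance-binned LD summary curves (average r-squared and mean
    max r-squared), tag-SNP tables at medium/high/perfect LD thresholds,
    frequency-matched tagging, a Li-Stephens-style haplotype-copying
    imputation engine with leave-one-individual-out evaluation stratified
    by genotype class (ref/ref, ref/alt, alt/alt), an r-squared-binned
    imputation experiment, and a seeded founder-mosaic simulator that
    writes phased VCF panels with an indel overlay so every stage is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    Rcpp,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
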