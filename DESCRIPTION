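Package: gencompat
Title: Genomic Compatibility Metrics for Assisted Gene Flow
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Evaluates donor-recipient genomic compatibility for assisted
    gene flow and genetic rescue planning. Partitions per-individual
    mutation load into masked (heterozygous) and realised (homozygous)
    components for loss-of-function and damaging missense variants, counts
    the novel functional mutations a donor genome would add to a recipient
    population (M_add), scores the net Mendelian F1 masking/unmasking
    potential of each donor-recipient genome pair (P_mask), and screens
    putatively adaptive variants for local adaptation with a per-SNP
    Weir-Cockerham F_ST scan against a gene-desert neutral null. Includes
    VCF ingestion with GATK-style hard filters and site filters, functional
    classification from effect annotations and PROVEAN scores, and a
    synthetic multi-population diploid cohort generator with closed-form
    expectations for every metric.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    jsonlite,
    purrr,
    readr,
    rlang,
    rtracklayer,
    S4Vectors,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    vcfR
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
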