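Package: histmarkr
Title: Comparative ChIP-Seq Analysis of Histone Methylation Marks Between
    Cell Lineages
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparing genome-wide H3K4me1 and H3K4me3 ChIP-seq
    enrichment between two cell lineages: partitioning a genome into proximal
    promoter, exon, intron and intergenic classes; a simplified local-Poisson
    sliding-window peak caller; classification of peaks as common or
    lineage-specific by 1-bp overlap; promoter and gene level enrichment
    tables with cross-lineage correlation; normalised metagene tag-density
    profiles over upstream flank, scaled gene body and downstream flank; and
    a seeded synthetic-data generator that plants peak architectures with
    ground-truth labels for end-to-end validation. All user-facing functions
    take and return tibbles.
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
    readr,
    stringr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    withr,
    GenomicRanges,
    IRanges,
    S4Vectors,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
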