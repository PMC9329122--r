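Package: drscan
Title: Depletion Rank Scoring of Genomic Windows from Population Variant Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Scores 500-bp genomic windows for depletion of sequence variants
    relative to a heptamer-context mutation model, assigning each window a
    Depletion Rank (DR) percentile from 0 (most depleted, strongest
    constraint) to 100 (least depleted). Includes construction of per-base
    reliability masks from coverage statistics, strand-collapsed mutation
    class logic, germline methylation calling from bisulfite counts,
    mutation-class saturation and de novo recurrence statistics, downstream
    enrichment statistics (fraction of rare variants by DR, annotation tail
    enrichment, odds ratios, gene-level regressions against external
    constraint scores), union-relative dataset overlap tables, and a seeded
    synthetic-data generator so the full analysis is exercisable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    stringr,
    readr,
    ggplot2,
    jsonlite,
    yaml,
    generics,
    withr,
    stats,
    utils,
    tools,
    methods,
    S4Vectors,
    IRanges,
    BiocGenerics,
    Biostrings,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
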