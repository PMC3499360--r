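Package: metachip
Title: Metagene Profiling and Promoter-Peak Persistence Analysis of
    Heterochromatin ChIP Tiling Signal
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for region-stratified analysis of ChIP tiling-array
    enrichment of heterochromatin proteins and histone marks (HP1a,
    H3K9me2/me3) across wild-type and methyltransferase-mutant genotypes:
    eight-feature average gene (metagene) profiles, detection and
    persistence classification of methylation-independent promoter peaks,
    peak-centered co-factor profiles, promoter sequence statistics (A/T
    content, position-weight-matrix motif scores, Mann-Whitney group
    comparisons), binary chromatin-factor co-occupancy with a prevalence
    filter, and DNase cleavage-density metagenes. Includes a seeded
    synthetic-data generator that emulates the signal structure of
    heterochromatic chromosome domains so the whole pipeline runs and is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    dplyr,
    GenomicRanges,
    S4Vectors,
    generics,
    ggplot2,
    purrr,
    rlang,
    rtracklayer,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
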