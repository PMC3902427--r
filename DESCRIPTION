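Package: ramscan
Title: Sliding-Window Detection of Regions of Altered Methylation from
    Methylation-Enrichment Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tiered sliding-window pipeline for calling regions of altered
    methylation (RAMs) from aligned methylation-enrichment sequencing reads
    (MeDIP/MethylPlex-style libraries). The genome is tiled into overlapping
    100 bp windows, per-window read counts are tested between exposure groups
    with a negative-binomial likelihood-ratio test using a common dispersion,
    and significant windows are filtered by per-sample support and adjacency
    before annotation against CpG-island shores and shelves, gene features,
    and promoters. Includes promoter dose-response classification, an
    empirical maximum-FDR estimate from a male-versus-female contrast, and a
    synthetic-data module that simulates enrichment-sequencing reads with
    planted monotonic and non-monotonic differential regions so the full
    analysis can be exercised and benchmarked at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
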