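Package: doublechec
Title: High-Confidence Transcription Factor Binding Sites from ChEC-seq
    Cleavage Maps
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Calls high-confidence transcription factor binding sites from
    ChEC-seq style single-base cleavage data. Aligned reads are reduced to
    the cleavage-adjacent base, normalized to counts per million, smoothed
    with a 3-bp sliding window, filtered against the genome-average
    baseline, and tested for enrichment over a soluble-MNase accessibility
    control with a negative-binomial Wald test. Enriched cleavage peaks
    15-50 bp apart are paired into doublets flanking protected binding
    sites and merged into single high-confidence intervals. Includes
    motif-anchored footprint metaplots, target-gene assignment with
    Fisher-exact overlap enrichment against curated target catalogs, and a
    synthetic-data simulator with planted sites for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    Rsamtools,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
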