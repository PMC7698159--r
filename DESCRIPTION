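Package: budclock
Title: Seasonal Bud Transcriptome Time-Series Analysis
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Downstream analysis of a replicated, calendar-dated bulk RNA-seq
    time series from overwintering perennial buds. Computes CPM and RPKM
    expression matrices from featureCounts-style count tables, correlates
    keyword-defined gene sets (e.g. heat-shock proteins) with a daily
    air-temperature series using Spearman rank correlation calibrated
    against random gene sets of matched size and expression cutoff, ranks
    candidate qRT-PCR reference genes by a standard-deviation-over-median
    stability score, summarises marker-gene time courses and
    transcription-factor family heatmaps, computes photoperiod (day length)
    for the sampling location, and ships a negative-binomial synthetic-data
    generator with planted gene classes so the whole pipeline is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    rtracklayer,
    GenomicRanges,
    pheatmap
Config/testthat/edition: 3
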