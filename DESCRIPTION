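Package: loopmet
Title: Enhancer-Promoter Loop, Nascent Transcription, m6A and 13C-Tracing
    Integration for Senescence Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Integrative analysis of chromatin-loop, transcription, RNA
    methylation and metabolic-tracing readouts in cellular senescence.
    Filters HiChIP loops by significance, classifies them by genomic
    distance, assigns enhancer-promoter (EP) interactions to genes via
    promoter windows and counts per-gene EP changes between conditions;
    balances Hi-C contact matrices by iterative correction (ICE); couples
    EP changes to nascent-transcription fold changes through grouped
    resampling and Pearson correlation; runs a knockdown candidate-gene
    funnel; classifies polymethylated m6A transcripts and intersects them
    with downregulated genes; corrects 13C isotopologue intensities for
    natural abundance by non-negative least squares and screens
    metabolites with a three-criterion t-test rule; and provides delta
    delta Ct quantitation utilities. A synthetic-data generator with
    planted ground truth exercises every stage without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    pracma,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
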