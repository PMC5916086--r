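Package: mateTiming
Title: Timing of Pheromone-Induced Gene Expression from Single-Cell
    Fluorescence Traces
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis of single-cell time-lapse reporter traces from the
    budding yeast mating pathway. Computes nuclear enrichment of dynamic
    expression reporters, basal-corrected traces, expression outputs and
    threshold-crossing response times; paired response-time delays between
    two reporters in the same cell with an exact sign test; correlative
    promoter variability (the intrinsic-to-total noise ratio of a dual
    reporter pair) over time; Hill dose-response fits and early/
    intermediate/late promoter classification; fusion-event detection and
    fusion-aligned expression timing for mating experiments; and a scanner
    for pheromone response elements (Ste12 binding sites) in promoter
    sequences with nucleosome-overlap annotation. Includes a synthetic
    trace generator with full ground truth so every stage of the pipeline
    can be validated by parameter recovery.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    IRanges,
    minpack.lm,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    rtracklayer
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
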