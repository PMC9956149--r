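Package: fociquant
Title: Threshold-Based Quantification of Fluorescent Protein Aggregates,
    Aggregation Kinetics, Cytotoxicity, and tRNA Abundance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying fluorescent protein aggregation in cultured
    cells and its companion assays. Detects sub-cellular aggregate foci in
    fluorescence microscopy frames with a stringent per-cell intensity
    threshold, converts thresholded areas into cell and aggregate counts by
    median size adjustment, and assembles per-frame quantities into
    aggregation time courses with fold-change, plateau, and cell-rupture
    (saw-tooth) analysis. Also computes dye-exclusion cytotoxicity ratios,
    aggregated-protein fractions from SDD-AGE lane densitometry, and
    isodecoder-resolved tRNA read-count statistics (pooling of identical gene
    copies, total-count normalization, differential abundance, pool
    fractions). A synthetic-data generator with known ground truth emulates
    transfected-cell images, time lapses with rupture events, count tables,
    toxicity plates, and lane profiles, so that every stage of the pipeline is
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    EBImage,
    igraph,
    jsonlite,
    stats,
    tiff,
    utils,
    zoo
Suggests:
    optparse,
    png,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
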