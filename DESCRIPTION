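Package: mavemap
Title: Scoring and Clinical Calibration of Multiplexed Variant Effect Maps
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for turning tile-sequencing counts from multiplexed
    assays of variant effect (deep mutational scans run under selection,
    e.g. yeast complementation) into calibrated functional score maps.
    Implements marginal counting at codon resolution, wild-type-control
    corrected enrichment log ratios, rescaling to synonymous/nonsense
    anchors, Baldi-Long variance regularization with bootstrap error
    propagation, read-support and replicate-consistency quality filters,
    a high-confidence ("HiQ") subset filter, kernel-density calibration
    of scores to log-likelihood ratios of pathogenicity mapped onto
    ACMG/AMP evidence strengths, balanced precision-recall evaluation,
    and map-level statistics (positional medians, annotation-stratified
    comparisons, moving-window stability correlations, case-control odds
    ratios). A synthetic-data generator simulates complete tile-seq
    selection experiments with known ground-truth variant fitness so the
    full pipeline can be exercised and validated without raw sequencing
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    Biostrings
Config/testthat/edition: 3
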