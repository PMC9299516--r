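Package: nociceptR
Title: Reactive-Cell Fraction Analysis for Calcium Imaging of Nociceptor Cultures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for single-cell calcium-imaging experiments on
    nociceptor-enriched sensory neuron cultures. Converts fluorescence image
    stacks or per-cell trace tables into stimulus-evoked fluorescence changes
    (delta F), applies a well-specific noise-based reactivity threshold
    (mean + 3 SD of negative-control responses, with a fixed upper cap) to
    obtain the fraction of reactive cells, and supports double-stimulation
    overlap analysis, concentration-response (EC50/IC50) fitting, and drug
    pre-treatment comparisons. A companion transcriptome module computes CPM,
    a simplified differential-expression filter, gene-ontology
    over-representation, and gene-set activation-score trajectories across
    maturation time points. Includes a seeded synthetic-data generator with
    ground truth for validation of every stage.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tiff,
    yaml,
    EBImage,
    fgsea,
    minpack.lm,
    multcomp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
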