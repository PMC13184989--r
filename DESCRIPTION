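Package: selscape
Title: Enrichment and Sequence-Activity Landscape Analysis for Single-Step In Vitro Selections
Version: 0.1.0
Authors@R:
    person("Selscape", "Developers", email = "selscape@example.org", role = c("aut", "cre"))
Description: Tools to analyse single-step in vitro selections of catalytic
    DNA (deoxyribozyme) libraries sequenced at high depth. Models degenerate
    bulge-library genotype spaces (IUPAC templates with paired-position
    constraints) and their exact combinatorics; converts merged amplicon
    reads into counts-per-million (CPM) genotype tables; scores substrate
    specificity as the log2 CPM ratio between two selection arms; stratifies
    specificity by variable position to rank mutation effects against a
    permutation null; and fits one-hot-encoded multilayer-perceptron
    regressions of CPM and specificity with nested training-set downsampling
    learning curves and positional-frequency baselines. A seeded selection
    simulator with a configurable genotype-to-activity landscape provides
    ground truth for parameter-recovery testing of the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    methods,
    stats,
    utils,
    tools,
    Biostrings
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
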