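Package: mtscreen
Title: Plate-Based Hit Calling and Downstream Analytics for 3D Microtissue Cytokine Screens
Version: 0.1.0
Authors@R: person("Microtissue Screen", "Maintainers", email = "maintainers@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for phenotypic high-throughput screens read out
    by multiplex cytokine profiling of 3D microtissues. Implements
    percent-decrease normalization against vehicle (DMSO) controls,
    negative-control-anchored hit thresholds with a configurable floor,
    diameter-based viability exclusion, Z-prime factor assay quality control,
    hit ranking and cross-platform intersection, longitudinal fluorescent-count
    survival summaries (net death, trapezoidal AUC, exponential-decay fits)
    with Sidak-adjusted group comparisons, differential secretome statistics
    (log2 fold change, unpaired t, Benjamini-Hochberg q-values), and cell-type
    composition statistics over time. Ships seeded synthetic-data generators
    with known ground truth so every analysis stage is testable end to end
    without external data, plus a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
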