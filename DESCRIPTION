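Package: mtsegsim
Title: Simulation and Analysis of Mitochondrial DNA Heteroplasmy Segregation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Stochastic simulators and analysis tools for the mitotic
    segregation of heteroplasmic mitochondrial DNA (mtDNA) in cultured cell
    clones. Implements random molecule-level vegetative segregation through
    cell-culture passages (growth to confluence, 1/10 bottlenecks, relaxed or
    strict replication, optional intra-cycle turnover), the metastable
    heteroplasmic segregation-unit model (faithful replication and random
    partitioning of multi-copy units, reorganization events, neutral fixation
    arithmetic), an observation model for padlock-probe/rolling-circle
    amplification (Padlock/RCA) single-cell dot counts with low per-molecule
    detection efficiency, and single-cell mutation-load histogram analysis
    with dots-per-cell stringency rules, subpopulation detection and
    peak-spacing inference of the segregation-unit copy number. A synthetic
    data generator composes all layers into complete in silico experiments
    with known ground truth.
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
    testthat (>= 3.0.0)
Config/testthat/edition: 3
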