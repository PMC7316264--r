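Package: restconn
Title: Resting-State Functional Connectome Construction and Mixed-Design
    Network Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Builds Fisher-z functional connectivity matrices from ROI BOLD
    time series (initial-volume discard, nuisance regression, polynomial
    detrending, zero-phase band-pass filtering), derives a group consensus
    structural backbone and backbone-masked mixed matrices, computes
    within-network connectivity strength and weighted global and local
    efficiency on named node sets, and tests every edge and network metric
    with a mixed two-way (Group x Timepoint) ANOVA under Benjamini-Hochberg
    false-discovery-rate control, extracting the significant subnetwork.
    Includes a synthetic cohort generator with planted Group x Timepoint
    connectivity effects so the full pipeline is testable end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
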