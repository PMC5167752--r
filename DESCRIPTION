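Package: bna
Title: Spatiotemporal Brain Network Activation Analysis for Event-Related Potentials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Segments multi-channel event-related potentials (ERPs) into
    spatiotemporal parcels (STEPs), clusters them across subjects into a
    group-level brain network activation (BNA) model with latency
    synchronization edges, scores individual subjects against the reference
    model (topographic similarity, global field power, connection timing),
    and evaluates condition discrimination with a linear support vector
    machine, ROC/AUC, and test-retest intraclass correlation. Includes a
    synthetic auditory-oddball ERP simulator with known ground truth so the
    whole pipeline can be exercised without real EEG recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
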