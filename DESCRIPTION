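Package: lamwave
Title: Laminar Analysis of Extracellular Waveforms and Spike Trains
Version: 0.1.0
Authors@R:
    person("lamwave", "maintainers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: Structure-function analysis of laminar high-density extracellular
    recordings (Neuropixels-style) from primary visual cortex. Curates
    spike-sorted units, clusters normalized action-potential waveforms with the
    WaveMAP procedure (UMAP fuzzy graph plus Louvain community detection),
    anchors unit depths to laminar boundaries estimated from current source
    density, and computes downstream functional characterizations: direction
    and orientation selectivity, modulation ratio, peri-stimulus time
    histograms and latency, inter-spike-interval PCA and a bursting index,
    multichannel action-potential propagation velocities with an asymmetry
    index, and jitter-corrected spike-train cross-correlograms with a lead-lag
    connectivity graph. Includes a seeded synthetic-cohort generator with known
    ground truth for every downstream estimator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    igraph,
    uwot,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
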