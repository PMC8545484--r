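Package: microquant
Title: Quantification of Microglial Calcium Activity, Synaptic Puncta,
    Phagocytosis, Spatial Distribution and Synaptic Currents
Version: 0.1.0
Authors@R: person("Pipeline", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A reusable, tested pipeline for the bespoke quantifications used
    in studies of microglial synapse pruning: detection of spontaneous GCaMP
    calcium transients from ROI fluorescence time series (dF/F normalisation,
    shape-preserving piecewise-cubic baseline, SD-scaled threshold and
    integral-area filter), quantification of presynaptic/postsynaptic puncta
    and colocalised synapses from two-channel 8-bit images (rolling-ball
    background subtraction, fixed-range thresholding, connected-component
    particle analysis with size exclusion, engulfment inside microglial
    masks), microbead phagocytosis indexing, nearest-neighbour spatial
    statistics of microglial somata (density, NND, regularity index),
    synaptic-current analysis around TTX application (event detection,
    window frequencies, Gaussian-histogram holding currents, agonist-induced
    current shifts, Nernst reversal potentials from solution recipes), and a
    synthetic-data module that generates every input with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
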