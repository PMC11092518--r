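Package: gridcan
Title: Spiking Continuous Attractor Network Model of Entorhinal Grid Cells
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates grid-cell activity in layer II of the medial entorhinal
    cortex with a spiking continuous attractor network. Neurons follow the
    nine-parameter Izhikevich formalism with population-specific excitability;
    synapses follow the Tsodyks-Markram short-term-plasticity model driving
    fast and slow conductance channels with reversal-potential currents.
    Stellate grid cells interact exclusively through three types of
    fast-spiking interneurons wired in a center-surround geometry on a
    toroidal neural sheet; velocity-tuned conjunctive cells and hippocampal
    place cells supply external drive. The package includes a synthetic
    open-field foraging trajectory generator, the full spatial analysis stack
    (occupancy-normalized rate maps, spatial autocorrelograms, grid score,
    grid-field size and spacing), spike-train rhythm analysis (multitaper
    power spectral density, band-power fractions, spike-phase coupling with
    the Rayleigh test), and grid-score parameter-robustness sweeps.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    signal,
    stats,
    utils,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
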