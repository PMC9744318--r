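Package: spindlenet
Title: Thalamocortical Network Model of Slow Oscillations and Sleep Spindles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Conductance-based six-layer thalamocortical network model of
    NREM sleep. Two cortical layers (two-compartment pyramidal cells and
    interneurons) generate ~1 Hz slow oscillations driven by miniature
    synaptic currents; two parallel thalamic relay/reticular subnetworks
    generate fast (12-16 Hz) and slow (8-12 Hz) sleep spindles, the slow
    subnetwork held at a more hyperpolarized level and coupled to cortex
    with a 600 ms conduction delay. Includes the full Hodgkin-Huxley
    channel kinetics, first-order AMPA/NMDA/GABA-A synapses with
    short-term depression, a second-order GABA-B G-protein cascade, a
    fixed-step network integrator (in C++), stimulation protocols and
    network manipulations (layer blocking, leak-conductance overrides,
    subnetwork swaps), and an analysis pipeline for local field
    potentials, spectra, slow-oscillation cycle segmentation and spindle
    event statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    tibble,
    dplyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    signal,
    stats
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
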