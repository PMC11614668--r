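Package: hvcnet
Title: Conductance-Based Model of the Zebra Finch HVC Premotor Network
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulator for the premotor nucleus HVC of the zebra finch song
    system. Implements conductance-based Hodgkin-Huxley models of HVC_RA
    projection neurons and HVC interneurons (including a T-type calcium
    current with Goldman-Hodgkin-Katz flux and a hyperpolarization-activated
    current), kinetic AMPA and GABA_A synapses driven by a sigmoidal
    transmitter-release function, and an A11 neuromodulatory trigger pulse
    that gates song-motif initiation. Networks are integrated with a
    fixed-step fourth-order Runge-Kutta scheme; analysis tools cover spike
    detection, burst grouping, rheobase search, chain-propagation summaries
    and parameter-robustness sweeps over synaptic conductances.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    graphics,
    jsonlite,
    stats,
    utils
Suggests:
    deSolve,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
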