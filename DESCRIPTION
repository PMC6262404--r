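Package: serialmem
Title: Serial-Order Sequence Memory in Spiking Winner-Take-All Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Clock-driven simulator for a neuromorphic serial-order memory
    architecture: soft winner-take-all (dynamic neural field) populations of
    adaptive exponential integrate-and-fire neurons, calcium- and
    voltage-gated bistable synaptic plasticity, and an ordinal / memory /
    content / condition-of-satisfaction network that learns, replays and
    overwrites sequences of items. Includes stimulation-protocol generators
    (Poisson inputs with Gaussian spatial profiles, go / transition / reset
    signals), a synthetic event-camera (address-event) front end, probe
    readout of plastic weights, bump detection and sequence decoding, and
    plain-text file formats for rasters, weight matrices and experiment
    configurations.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
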