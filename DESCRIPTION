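Package: klinfo
Title: Information Flow Through a Model C. elegans Klinotaxis Circuit
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation and information-dynamics analysis of the minimal
    salt-klinotaxis circuit of the nematode C. elegans.  Provides a
    deterministic model of the circuit (idealized ON/OFF chemosensors,
    passive isopotential interneurons and neck motor neurons with an
    antiphase oscillatory pattern-generator drive, and a point-body model
    of undulatory locomotion), a genetic algorithm that evolves ensembles
    of klinotaxis-competent circuits under a dorsal/ventral symmetry
    constraint, open-loop concentration-step and information-clamp assays,
    and time-resolved information measures (normalized mutual information,
    stimulus-specific information, and transfer entropy) estimated with
    average shifted histograms, from which the circuit's information
    architecture is reconstructed.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
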