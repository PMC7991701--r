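Package: willisim
Title: 1D-0D Hemodynamic Simulation of Cerebral Perfusion During
    Carotid Clamping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates pulse-wave propagation in a population-averaged
    arterial network including the circle of Willis, closed by lumped
    (0D) Windkessel outlets, autoregulating cerebral vascular beds and a
    trans-stenotic pressure-loss element.  Provides the virtual-patient
    protocol for carotid endarterectomy planning: clamping of one
    internal carotid artery, a stenosis sweep on the contralateral
    internal carotid artery, extraction of carotid stump pressure,
    communicating-artery flow redistribution and cerebral peripheral
    pressures, threshold detection on the sweep, and the duplex
    stenosis-grading and stump-pressure shunt decision rules.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    optparse,
    withr
Config/testthat/edition: 3
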