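Package: dqskit
Title: Dynamical Quorum Sensing Onset Analysis from Cellular Response Spectra
Version: 0.1.0
Authors@R:
    person("DQS", "Maintainers", email = "dqskit@example.org", role = c("aut", "cre"))
Description: Tools for analysing the emergence of collective oscillations in
    communicating cell populations (dynamical quorum sensing). Implements
    frequency-resolved linear response spectra with fixed phase conventions,
    Kramers-Kronig reconstruction, fluctuation-dissipation diagnostics and
    cell-to-signal energy flux; solves the phase-matching and gain conditions
    for the onset frequency and critical cell density; provides stochastic
    simulators for an adaptive two-node circuit with cubic nonlinearity and
    for coupled FitzHugh-Nagumo populations; includes a reduced model of
    yeast glycolytic oscillations coupled through extracellular acetaldehyde,
    and a fixture generator for step-response pipelines.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
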