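Package: bacsim
Title: Within-Host Bacteria-Immune Response Simulation Toolkit
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Scriptable simulation of simple within-host bacteria and
    immune-response dynamics. A declarative model specification (variables,
    parameters, signed rate terms, and a stochastic event decomposition)
    drives three interchangeable backends: a continuous ordinary
    differential equation solver, a discrete-time forward-Euler update, and
    an exact stochastic simulation algorithm (Gillespie direct method). Two
    compartmental predator-prey-type models are bundled: logistic bacterial
    growth with mass-action immune activation, and a variant in which immune
    activation saturates at high bacterial load. Outcome metrics (peak and
    final value) and one-parameter logarithmic sweeps support exploration of
    peak-load response curves, and a small command-line interface exposes
    listing, describing, running, and sweeping the bundled models with CSV
    and PNG output.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    deSolve,
    jsonlite,
    yaml,
    grDevices,
    graphics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
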