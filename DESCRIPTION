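Package: phagetrain
Title: Serial-Transfer Simulation of Directed Phage Host-Range Evolution
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Deterministic simulation of lytic phage competition during
    directed host-range evolution by serial transfer. Models free phage,
    infected cells and exponentially growing bacteria with strain-specific
    burst sizes, lysis rates and adsorption constants; orchestrates
    Parallel, Sequential and Mixed host-presentation protocols with
    fixed-count, fixed-volume and per-host dilution regimes; sweeps
    generalist burst sizes to map retention of generalist versus specialist
    phages; and provides closed-form per-cycle selection ratios and
    mutant bottleneck-survival arithmetic.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    deSolve,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
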