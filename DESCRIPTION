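Package: clhomeo
Title: Chloride Homeostasis Analysis for Voltage-Clamp Ramp Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying neuronal chloride homeostasis from
    voltage-clamp ramp recordings. Provides a seeded synthetic-sweep
    generator emulating zigzag ramp protocols with series-resistance
    voltage error, exchange-filtered agonist conductances and coupled
    intracellular chloride dynamics; series-resistance correction,
    voltage re-gridding and model-based leak subtraction of I-V curves;
    reversal-potential and slope-conductance extraction; the relative
    resting chloride conductance estimator based on the shift of the
    total-current reversal potential relative to the shift of the
    chloride Nernst potential; a single-compartment forward-Euler model
    of KCC2-mediated and conductive chloride fluxes with analytic steady
    states; and exponential recovery-kinetics fitting with normalized
    recovery summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    minpack.lm,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    deSolve,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
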