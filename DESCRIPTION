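Package: sensotherm
Title: Stochastic Thermodynamics of Information Processing in Sensory Adaptation
Version: 0.1.0
Authors@R:
    person("Sensotherm", "Developers", email = "sensotherm@example.org",
           role = c("aut", "cre"))
Description: Tools for the stochastic thermodynamics of sensing in
    signal-driven finite-state Markov models. Provides continuous-time
    master-equation machinery conditioned on a binary signal-switch
    protocol, mutual-information ledgers tracking how information about a
    new signal is measured while information about the old signal is
    erased, entropy-production decompositions (measurement/erasure and
    nonadiabatic/adiabatic), and excess heat and work accounting with
    Landauer-type bounds. Ships two bundled sensors: a four-state
    equilibrium feedforward adaptive module and a ten-state nonequilibrium
    E. coli chemoreceptor with methylation memory driven by SAM
    hydrolysis, together with figure-level experiment drivers, a random
    model fixture generator, and a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
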