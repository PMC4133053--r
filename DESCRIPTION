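Package: kinmem
Title: Kinetic Memory in Enzyme-Limited Protein Modification Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulators and analysis tools for multisite protein modification
    kinetics in the enzyme-limited competition regime. Implements three
    reduced (fast binding equilibrium) models -- a chained modification model
    with uncatalysed modification and catalyst-limited demodification, a
    kinase-phosphatase model, and an extended two-state Asakura-Honda
    receptor model -- together with full mass-action reference models,
    rigorous free-catalyst conservation-law solvers, relaxation-time and
    decay-class observables, an asymptotic estimator of the slow logarithmic
    relaxation, and scripted parameter sweeps (relaxation time versus
    catalyst abundance, stimulus magnitude x duration memory maps).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    Matrix,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
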