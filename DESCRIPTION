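Package: klsdyn
Title: Dynamical Transitions in the One-Dimensional Katz-Lebowitz-Spohn
    Exclusion Process
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for the one-dimensional Katz-Lebowitz-Spohn (KLS) driven
    lattice gas with Glauber hopping rates and bulk-adapted open boundary
    conditions, a generalization of the totally asymmetric simple exclusion
    process (TASEP) used to model ribosome and molecular-motor traffic.
    Provides exact bulk nonequilibrium steady-state solutions and fundamental
    diagrams, extremal-current phase classification, pair-approximation
    kinetic equations with stationary profiles and relaxation spectra,
    domain-wall theory (plain and modified) relaxation rates, numerically
    exact finite-size spectral gaps of the master equation with
    Bulirsch-Stoer extrapolation to infinite size, and rejection-free
    kinetic Monte Carlo simulation, together with a command-line interface
    for parameter scans.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    deSolve,
    jsonlite,
    yaml,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
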