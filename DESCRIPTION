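Package: compthermo
Title: Stochastic Thermodynamics of Composite Markov Processes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the stochastic thermodynamics of composite processes:
    finite collections of co-evolving subsystems whose joint continuous-time
    Markov dynamics is mediated by shared mechanisms that may move several
    subsystems at once.  Provides a declarative process model (subsystem state
    spaces, dependency networks, mechanisms with puppet and leader sets),
    exact master-equation propagation and Gillespie trajectory sampling,
    mechanism-resolved decompositions of probability flows, dynamical
    activity and entropy production, inclusion-exclusion decompositions of
    entropy production over unit structures, mismatch-cost and periodicity
    lower bounds on entropy production, thermodynamic uncertainty relations
    for mechanism-specific and information-flow currents, and strengthened
    thermodynamic speed limits.  A mass-action reaction-network compiler
    builds composite processes on truncated count spaces.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    deSolve,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
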