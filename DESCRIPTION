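Package: NTRkinetics
Title: Steady-State and Pre-Steady-State Kinetics of Ping-Pong Nitroreductases
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing the two-substrate (ping-pong bi-bi) kinetics
    of flavin-dependent nitroreductases such as Escherichia coli NfsA.
    Implements the steady-state ping-pong rate law with dead-end (mixed)
    product inhibition in both half-reactions, global multi-dataset nonlinear
    least-squares fitting with AIC/AICc model selection among inhibition
    variants, single-exponential analysis of stopped-flow absorbance
    transients with hyperbolic concentration dependence of the observed rate
    constant, Beer-Lambert conversions using flavin extinction coefficients,
    a mass-action ODE simulator of the substituted-enzyme mechanism
    (including a half-of-sites dimer variant with negative cooperativity)
    that doubles as a brute-force oracle for the closed-form rate laws, and
    seeded synthetic-data generators emulating the standard experimental
    designs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    withr,
    jsonlite
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
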