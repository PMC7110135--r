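Package: rad51kin
Title: Mechanistic Models of RAD51 Polymerisation Kinetics on DNA
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing RAD51 nucleoprotein filament formation on
    single- and double-stranded DNA as observed by surface plasmon resonance
    (SPR). Implements the isodesmic steady-state distribution of RAD51
    polymers in solution governed by a single protomer-protomer dissociation
    constant, linear birth-death models of filament nucleation, elongation
    and dissociation on short DNA substrates, double-referencing and
    mass-ratio normalization of SPR sensorgrams, a synthetic sensorgram
    generator for parameter-recovery benchmarks, approximate Bayesian
    computation with sequential Monte Carlo (ABC-SMC) for joint kinetic
    parameter inference, and bounded least-squares single-parameter refits.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
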