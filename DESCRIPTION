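Package: protacscreen
Title: Ligand-Centric Ternary-Complex Screening and SPR Cooperativity
    Analysis for Rigid-Linker PROTACs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for predicting ternary complex geometries of PROTAC
    degraders with rigid diyne linkers and for analysing the surface plasmon
    resonance (SPR) kinetics of ternary complex formation. Implements a
    ligand-centric modelling pipeline: systematic enumeration of linker
    dihedral conformers, rigid-body (Kabsch) superposition of the two
    protein-ligand complexes onto the PROTAC warheads, steric clash
    screening of the resulting poses, a staged harmonic-restraint
    relaxation schedule with trajectory bookkeeping, and medoid
    (lowest-median-RMSD) representative frame selection. The SPR side
    simulates and globally fits 1:1 Langmuir binding kinetics for binary
    and pre-mixed ternary formats, deriving dissociation constants,
    complex half-lives, and the cooperativity factor alpha. A synthetic
    data generator plants scenes and sensorgrams with known ground truth
    so every stage is testable without external structure downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    rlang,
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    deSolve,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
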