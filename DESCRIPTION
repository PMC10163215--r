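Package: genosensr
Title: Label-Free Genotyping of BRCA1 Founder Mutations from SPR and
    QCM-D Hybridization Kinetics
Version: 0.1.0
Authors@R:
    person("genosensr", "developers", email = "genosensr@example.org",
           role = c("aut", "cre"))
Description: Tools for label-free DNA-hybridization genotyping with
    surface plasmon resonance (SPR) and quartz crystal microbalance with
    dissipation monitoring (QCM-D). Simulates and fits 1:1 Langmuir
    binding kinetics of probe-target duplex formation (association and
    dissociation rate constants, equilibrium constants), classifies
    mutation status by an association-equilibrium-constant threshold
    relative to a fully complementary synthetic reference, analyses
    dissipation-versus-frequency slopes for gravimetric calls, and
    evaluates diagnostic specificity and selectivity on truth-labelled
    cohorts. Ships the oligonucleotide panels, kinetic constants and
    genotyping outcomes of a published five-panel BRCA1 founder-mutation
    study as plain-text fixtures, plus a synthetic-cohort generator so
    the whole pipeline is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    optparse,
    stats,
    tools,
    utils
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
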