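Package: specbind
Title: Spectroscopic Analysis of Protein-Ligand Binding
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Analysis pipeline for steady-state spectroscopic studies of
    protein-ligand binding: inner-filter correction and Stern-Volmer
    fluorescence quenching, modified Stern-Volmer binding constants and
    stoichiometry, van't Hoff thermodynamics with interaction-force
    classification, circular dichroism mean residue ellipticity and
    alpha-helix content, ANS displacement summaries, and Forster resonance
    energy transfer (overlap integral, Forster radius, donor-acceptor
    distance). Includes a synthetic titration/spectrum generator so every
    stage is testable without instrument output, plain-text spectrum and
    manifest readers, and a command-line interface.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    pracma,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
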