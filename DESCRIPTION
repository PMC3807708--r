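Package: affidesign
Title: Computer-Aided Design of Affinity-Modulating Receptor Interface Mutations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for structure-based design of receptor mutations
    that modulate binding affinity to a protein ligand, developed around the
    interferon-gamma / interferon-gamma receptor 1 system. Identifies
    protein-protein interface residues from crystal structures by a distance
    criterion, filters mutation candidates through per-column sequence
    conservation of a multiple sequence alignment, selects single and multi-site
    mutants from externally computed stability and affinity free-energy change
    (ddG) matrices, and provides the downstream biophysical analyses: conversion
    between dissociation constants and binding free-energy changes, additivity
    analysis of multi-mutants, Student-t confidence limits on replicate
    affinities, global fitting of surface plasmon resonance sensorgrams to the
    1:1 Langmuir-with-drift model, and melting-temperature estimation from
    thermal shift assay curves. Synthetic-data generators with planted ground
    truth make every stage testable without external structure downloads or
    wet-lab input.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    seqinr,
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    deSolve,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
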