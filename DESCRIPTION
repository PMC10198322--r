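Package: quadscan
Title: Semi-Orthogonal Scoring of Noncanonical Four-Stranded DNA Motifs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts noncanonical (four-stranded) DNA motifs from primary
    sequence using a semi-orthogonal projection score: each nucleotide is
    assigned a signed height on the G/C projection axis (A/T heights scale
    with the inclination angle psi), and the per-nucleotide area under the
    resulting polyline (the Qs score) quantifies quadruplex and i-motif
    propensity. Includes a sliding-window genome scanner with BED/TSV
    output, a score-band classifier for G-quadruplex, left-handed Z-G4,
    tetrahelical and i-motif candidates, a dinucleotide repeat-tract
    finder, a two-state van't Hoff melting-curve fitting module (Tm,
    enthalpy, free energy at a reference temperature, derivative-based Tm
    estimation), and deterministic synthetic-data generators for sequences,
    spiked genomes and melting curves.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    minpack.lm,
    signal,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
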