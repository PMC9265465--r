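Package: fqbiodeg
Title: Composite Biodegradability Scoring and QSAR Diagnostics for
    Fluoroquinolone Composting Studies
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantitative analysis of fluoroquinolone (FQ) biodegradability
    in sewage-sludge composting systems. Implements entropy-weighted
    composite scoring of ligand-receptor docking-score matrices, NIPALS
    partial least squares with leave-one-out q2 and external r2pred
    validation statistics for CoMFA-style 3D-QSAR models, steric and
    electrostatic molecular-field descriptors on a rectangular lattice,
    percent-change screening of antibiotic derivatives against
    environmental red lines, two-level factorial effect estimation with
    significance screening for unreplicated designs, and MM/PBSA
    binding free-energy bookkeeping, together with seeded synthetic-data
    generators so every stage is testable.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    bio3d
Config/testthat/edition: 3
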