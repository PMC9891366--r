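Package: latticemotifs
Title: Data-Driven Attribution of Molecular Crystal Lattice Energies to
    Functional-Group Motifs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to learn and interpret the lattice (binding) energy of
    organic molecular crystals from atom-centered structural descriptors.
    Reads periodic crystals and their gas-phase molecular constituents
    (extended XYZ, CIF), computes rotation-invariant three-body
    power-spectrum (SOAP-style) descriptors for both phases and forms the
    "remnant" solid-minus-gas representation, fits composition-baselined
    ridge models of per-atom and lattice energies with cross-validated
    regularization and farthest-point-sampled training sets, decomposes
    predictions into smoothed per-atom contributions, aggregates them over
    SMARTS-defined functional-group motifs with geometric hydrogen-bond
    detection, and arranges motif environments on supervised
    principal-covariates-regression (PCovR) maps supporting out-of-sample
    projection and latent-space similarity search.  A synthetic-crystal
    generator with planted atom-centered energetics makes the full pipeline
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
SystemRequirements: Python (>= 3.8) with RDKit, for SMARTS motif matching
Config/testthat/edition: 3
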