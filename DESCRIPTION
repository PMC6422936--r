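Package: muc3
Title: Simulation and Analysis of Neutrophil Migratory Decision-Making in a
    Dual-Gradient Microfluidic Chip
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to model and quantify single-cell migratory decision-making
    in a microfluidic competitive chemotaxis chip. Includes a finite-difference
    solver for chemoattractant gradient formation along the migration channels,
    an agent-based generator of single-cell migration tracks under
    lipopolysaccharide (LPS) priming presets, a synthetic nuclear-stain image
    renderer with automated spot detection and track linking, the full
    migration metric suite (percent migrated, accumulation rate, single-cell
    velocity, oscillatory and non-directional classification, decision ratios,
    spontaneous migration), and group-comparison reporting.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    yaml,
    jsonlite,
    tiff,
    EBImage
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
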