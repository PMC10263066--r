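Package: tilprofiler
Title: Immune Subtyping of Non-Small Cell Lung Cancer from
    Tumor-Infiltrating Leukocyte Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Classifies tumors into Cold, Myeloid and CD8 immune
    microenvironment subtypes from flow-cytometry profiles of
    tumor-infiltrating leukocytes.  Provides a declarative gating engine
    that resolves event-level marker intensities into 30 immune cell
    populations, dual-representation features (cell density per gram and
    percentage of CD45+ cells), unsupervised Ward.D2 clustering on
    Spearman correlation distance with an automated subtype labelling
    rule, and downstream characterisation: gene-signature scores,
    nearest-centroid molecular subtype assignment, cancer-immunity-cycle
    immunogram axes, T-cell receptor repertoire Shannon entropy, and
    survival / association scans with Holm-adjusted flagging.  A
    synthetic-cohort generator with planted subtype structure makes every
    stage testable without access to controlled patient-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    survival,
    yaml,
    jsonlite,
    ape
Suggests:
    testthat (>= 3.0.0),
    vegan,
    mclust
Config/testthat/edition: 3
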