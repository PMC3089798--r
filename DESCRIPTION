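Package: ahrcompare
Title: Cross-Species Comparative Analysis of Dioxin-Elicited Gene Expression
Version: 0.9.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A tested re-implementation of a cross-species comparative
    transcriptomics workflow for 2,3,7,8-tetrachlorodibenzo-p-dioxin (TCDD)
    responses in human, mouse and rat hepatoma cells. Provides synthetic
    two-color microarray and promoter data generators with ground truth,
    intensity-dependent dye-bias normalization, empirical-Bayes differential
    expression with posterior probabilities of activity P1(t), ortholog-anchored
    classification of responses as conserved, divergent or species-specific,
    cycloheximide-based primary/secondary response classification, and
    computational dioxin response element (DRE) promoter analysis with
    position-weight-matrix scoring and cross-species DRE conservation
    clustering.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    Biostrings,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    ape,
    limma
Config/testthat/edition: 3
RoxygenNote: 7.3.3
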