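Package: glycopose
Title: Pose Selection and Specificity Analysis for Antibody-Glycan Complexes
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for selecting a validated three-dimensional model of an
    antibody-glycan complex and for predicting antibody glycan specificity.
    Implements a docking-pose funnel (campaign bookkeeping, pose RMSD,
    density-based clustering and representative selection), a trajectory
    stability filter based on ligand RMSF, a proximity model for predicted
    saturation-transfer-difference (STD) NMR enhancements with an agreement
    score against experimental integrals, glycan-microarray quantification
    (one-site apparent-KD fits, relative-RFU ranking, alanine-scan ddG and
    mutant classification), and computational carbohydrate grafting of
    glycome entries onto a bound antigen core with steric-occlusion
    verdicts. Ships a glycan sequence parser, glycosidic rotamer
    enumeration, an idealized 3-D builder, and synthetic-data generators
    with known ground truth for every pipeline input.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    igraph,
    jsonlite,
    minpack.lm,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
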