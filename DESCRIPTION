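Package: pocketmolr
Title: Structure-Guided Binding-Pocket Model Induction and Affinity Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Induces sparse probe-based surrogate binding-site models
    ("pocketmols") from training ligands with activity data, optionally
    guided by an ensemble of aligned protein pocket structures, and
    predicts pKi, bound pose, and a similarity-based confidence for new
    molecules by flexible fitting. Includes 3D Gaussian-overlap molecular
    similarity, similarity-driven alignment, an empirical atom-probe
    scoring function with the multiple-instance max-pose rule, probe
    tessellation with structure-based filtering, greedy probe-subset
    selection with alternating probe/pose refinement, parsimony-based
    model selection, evaluation statistics (Kendall tau with permutation
    p-values, pose RMSD, pocket-probe concordance), and a seeded
    synthetic benchmark generator.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    bio3d,
    ChemmineR
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
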