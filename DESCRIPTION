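Package: metabotyper
Title: Metabotype Definition from Standard Clinical Parameters
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Defines metabotypes (metabolically homogeneous population
    subgroups) from a small panel of routinely measured clinical
    parameters. Provides a synthetic cohort generator with a planted
    three-group metabolic structure, exclusion and chained-equations
    imputation preprocessing, three tree-ensemble variable-importance
    methods (permutation importance with fitted null distributions,
    cross-validated permutation importance, and gradient-boosting gain)
    for selecting clustering parameters, consensus k-means clustering
    across multiply imputed data sets, and incidence-based evaluation
    and ranking of candidate metabotype models.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    cluster,
    ranger,
    xgboost,
    fitdistrplus,
    mclust,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
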