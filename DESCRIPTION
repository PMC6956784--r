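Package: dockrf
Title: Ensemble-Docking Metrics and Random-Forest Affinity Prediction
Version: 0.1.0
Authors@R:
    person("dockrf", "Maintainers", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Combined structure-based and ligand-based prediction of
    protein-ligand binding affinity. Aggregates per-pose docking metrics from
    ensemble docking into per-ligand unified instances (median and standard
    deviation over poses), computes ligand molecular descriptors and MACCS
    fingerprints, and trains random-forest regression models of p-affinity
    (pKi/pIC50) with repeated stratified cross-validation, a stratified
    hold-out protocol and cross-dataset evaluation matrices. Ships a
    synthetic-benchmark generator so the full pipeline runs offline without
    a docking stack.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    jsonlite,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
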