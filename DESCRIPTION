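Package: fingermatch
Title: Cross-Species Connectivity Fingerprint Matching
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Connectivity-based parcellation of a tracer connectome with
    silhouette model selection, seed-to-target connectivity fingerprints from
    resting-state timeseries with robust-mean templates and Manhattan-distance
    permutation tests, voxelwise cross-species fingerprint matching with
    sign-flip TFCE permutation inference, conjunction analysis of unassigned
    voxels, distribution-based anatomical localisation, and a synthetic-data
    generator with planted ground truth so every stage is testable without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    cluster,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    igraph,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
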