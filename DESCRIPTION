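Package: profclust
Title: Alignment and Centroid Clustering of Multi-Track Genomic Signal Profiles
Version: 0.1.0
Authors@R:
    person("Maintainer", "Package", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Exhaustive rigid-shift alignment (with optional mirroring) and
    unweighted pair-group centroid clustering of multi-track genomic signal
    profiles, such as binned ChIP-seq or ChIP-on-chip coverage around peak
    regions. Profiles are compared at every admissible shift in both
    orientations using a normalized sum-of-squared-distances score, merged
    into coverage-weighted average representatives, and pruned at sparsely
    aligned alignment edges. Includes parsers for BED, bedGraph and wiggle
    tracks with linear interpolation of missing signal, a synthetic
    planted-cluster data generator for validation, downstream statistics
    (orientation-annotation correlation, meta-profiles) and a command line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    parallel,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    ape,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
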