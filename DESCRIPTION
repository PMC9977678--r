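Package: spatcoloc
Title: Segmentation-Free Co-Localization Analysis for Imaging-Based
    Spatial Transcriptomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis of molecule-resolved spatial transcriptomics
    (molecular-cartography-style) data without relying on cell
    segmentation. Same-gene transcripts are grouped into spatial clusters
    by average-linkage hierarchical clustering with a fixed dendrogram
    cut, a fixed-radius neighbourhood graph is built over cluster
    centroids, and cross-type co-localization or avoidance is scored by a
    vertex-label permutation test aggregated into a signed
    fraction-of-slides proximity score. A segmentation-based branch
    expands nuclear label rasters, assigns transcripts to segments and
    quantifies double-positive segment fractions. A dual-channel spot
    module classifies active versus basal cells by nearest-neighbour
    distance and compares active-to-basal ratios between crypt thirds.
    A synthetic-data module generates marked point patterns with
    controllable co-localization, independence or avoidance, plus paired
    spot sets, so every stage is testable against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
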