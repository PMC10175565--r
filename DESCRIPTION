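Package: metalloc
Title: Geometric and Density-Based Prediction of Zinc Binding Sites in Protein Structures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to locate zinc ion binding sites in protein structures from
    geometry alone. Implements a coordination-environment probability map mined
    from PDB LINK records, residue scoring and score-weighted site placement
    (purely geometric prediction), an 8-channel voxelization of residue
    environments with a buildable fully convolutional 3D segmentation network
    and density post-processing (global grid averaging and cluster-based ion
    placement), the standard binding-site evaluation protocol (clustered 5 A
    matching, precision, recall, mean absolute deviation, discretized Jaccard
    index), and a synthetic metalloprotein generator so the whole pipeline is
    testable without external structure downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
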