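Package: cryotrace
Title: Multimodal Cryo-EM Map-to-Model Backbone Building
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds sequence-registered protein C-alpha backbone models from
    cryo-EM density maps, optionally fusing voxel encodings of predicted
    chain structures placed in the map frame. Provides density-map
    standardization (resampling to 1 Angstrom voxels, robust normalization,
    sliding-window partitioning), voxel label-mask preparation from reference
    structures, a multimodal 3D convolutional encoder-FPN-decoder network
    with multi-task weighted cross-entropy training, DBSCAN-based C-alpha
    candidate extraction with non-maximum suppression, connectivity-graph
    backbone tracing with N-hop score propagation and greedy sequence
    registration, gap filling guided by predicted structures, and
    model-quality metrics (TM-score, C-alpha match, C-alpha quality score,
    sequence match). Includes a synthetic-data module generating toy
    structures, simulated density maps and oracle probability volumes so the
    whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    bio3d,
    igraph,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
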