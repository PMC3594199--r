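Package: gmnet
Title: Single-Subject Grey Matter Similarity Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Extracts structural brain graphs from a single subject's grey
    matter segmentation by tiling the cortex into 3x3x3 voxel cubes,
    computing rotation-maximized Pearson similarity between all cube pairs,
    and binarizing the similarity matrix at a permutation-calibrated
    threshold that fixes the expected proportion of chance edges. Provides
    graph-theoretic characterization (degree, clustering, path length,
    betweenness, hubs), small-world normalization against degree-preserving
    randomized reference graphs, atlas-based regional summaries, and
    cohort-level statistics (rank-transform ANCOVA, Levene checks,
    correlations with cognitive scores, forward nested regression, FDR).
    Includes a synthetic-data generator with known ground truth so the whole
    pipeline is testable without MRI data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    RNifti,
    igraph,
    jsonlite,
    stats,
    utils,
    car,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
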