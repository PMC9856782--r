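Package: fdcovnet
Title: Fractal-Dimension Structural Covariance Networks for Cortical Morphometry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Box-counting fractal dimension (FD) estimation for 3D voxel
    objects and labeled cortical parcellations, group-level FD structural
    covariance networks with proportional thresholding, modularity-based
    community detection, intra-/inter-modular and lobe-level connectivity
    metrics (within-module degree z-score, participation coefficient), and
    statistical group comparison via regional t-tests with
    Benjamini-Hochberg correction, effect sizes, and subsample permutation
    tests on network properties. Includes phantom generators (cube, slab,
    Menger sponge) with known dimension and a two-group cohort simulator
    with planted covariance blocks and planted regional effects, so the
    full pipeline is testable without MRI data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    MASS,
    igraph,
    withr,
    RNifti,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite,
    optparse
Config/testthat/edition: 3
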