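Package: lfbmil
Title: Weakly Supervised Attention-Based Multiple Instance Learning for
    Myelin Histopathology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for weakly supervised classification of
    Luxol-fast-blue stained brain slide images from noisy cognitive labels.
    Slides are tiled into 256x256 patches, tiles are embedded into fixed-length
    feature vectors, and a gated attention-based multiple instance learning
    classifier is trained under Monte Carlo cross-validation. Per-tile attention
    supports interpretation: attention heatmaps, white-matter versus grey-matter
    attention statistics, and hue-range positive-pixel quantification of
    dark-blue myelin staining in top-attention tiles. Downstream statistics
    include rank correlations, permutation-based differential correlation, and
    chi-square conditional independence tests on contingency mutual information.
    A synthetic slide and cohort generator with planted myelin-loss effects
    provides ground truth for parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    MASS,
    png,
    jsonlite,
    tools
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
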