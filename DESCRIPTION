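Package: panelselect
Title: Differentiable Gene Panel Selection for Spatial Transcriptomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Selects compact, informative gene panels for targeted spatial
    transcriptomics (FISH/MERFISH) from reference scRNA-seq data. A predictor
    network is trained on binarized expression through stochastic relaxed
    selection layers (a Concrete binary-mask layer for exact panel sizes and a
    Binary-Concrete gates layer with a secant-tuned sparsity penalty for
    pre-filtering), optimising a hurdle loss that models dropout noise, or
    supervised objectives (cell-type classification, continuous cell
    properties). Includes the matching evaluation protocol (explained
    variance, expressed-gene prediction, gradient-boosted-tree cell-type
    accuracy, panel-overlap statistics), cross-technology binarization by
    per-gene quantile threshold matching, and a zero-inflated synthetic data
    generator with planted ground-truth genes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    optparse,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    xgboost,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
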