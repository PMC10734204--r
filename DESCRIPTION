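Package: circdrugnet
Title: circRNA-Drug Sensitivity Association Prediction via Dual
    Hierarchical Attention and Multi-Kernel Fusion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Predicts circRNA-drug sensitivity associations on a bipartite
    network. Builds sequence (Levenshtein-ratio), structure (Tanimoto on
    topological fingerprints) and Gaussian interaction-profile similarities,
    integrates them by nonlinear cross-diffusion fusion, learns node
    embeddings with a dual hierarchical (intra-type and inter-type)
    relation-aware attention encoder on a head/tail-typed heterogeneous
    graph, fuses per-layer Gaussian kernels over the embedding stack, and
    scores associations with Dual Laplacian Regularized Least Squares
    solved by exact alternating block updates. Includes a synthetic
    planted-block study generator, 5-fold cross-validation with seven
    metrics, ablation modes, and cold-start (ab initio) ranking.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    ChemmineR,
    ChemmineOB,
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
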