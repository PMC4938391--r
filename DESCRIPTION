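Package: tnlm
Title: Temporal Non-Local Means Filtering and Graph Parcellation of
    Surface-Sampled Resting fMRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Edge-preserving denoising of per-vertex BOLD time series on
    triangulated cortical surface meshes by temporal non-local means
    (tNLM), where filter weights derive from full time-series correlation
    rather than spatial proximity, together with a Laplace-Beltrami
    heat-kernel smoothing baseline, normalized-cuts spectral parcellation
    of the correlation-affinity graph, and an evaluation stack
    (Gale-Shapley stable label matching, concordance, task-label
    agreement, boundary maps). Includes a synthetic four-quadrant
    simulation generator with planted functional regions for validation,
    minimal GIFTI surface/functional/label I/O, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    igraph,
    jsonlite,
    xml2,
    tibble,
    generics,
    ggplot2,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
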