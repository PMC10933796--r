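Package: histoslice
Title: Deformable Registration of Stand-Alone Histology Sections to 3D MRI
Version: 0.1.0
Authors@R: person("histoslice", "developers", role = c("aut", "cre"),
    email = "histoslice@example.org")
Description: A four-stage pipeline for registering individual 2D histology
    sections to whole-organ 3D MRI volumes via two photographic
    intermediaries (tissue-block and brain-slab photographs). Provides a
    transformation-chain engine (rigid, affine, dense and control-point
    displacement fields, 2D-to-3D embedding) with Jacobians and vector
    reorientation, the modality-independent neighbourhood descriptor (MIND)
    similarity metric, diffusion-regularised Gauss-Newton deformable
    registration, bounded derivative-free optimisation, automatic
    sampling-site detection on slab photographs, hemisphere-chain merging,
    evaluation metrics (median contour distance, median registration
    error), and a synthetic phantom generator that makes every stage
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    minqa,
    png,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
NeedsCompilation: yes
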