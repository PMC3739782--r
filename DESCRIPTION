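Package: taphomorph
Title: Separating Taphonomic Deformation from Biological Shape Variation in
    3D Landmark Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for 3D geometric morphometrics of fossil skulls where
    post-mortem (taphonomic) deformation dominates the shape variation.
    Provides landmark file input/output (morphologika-style, TPS, CSV),
    landmark-scheme handling with exclusion rules, Generalized Procrustes
    Analysis with tangent-space projection, shape-space principal component
    analysis with broken-stick component selection, per-axis 95% confidence
    bands and outlier flagging, a replicate-digitization error protocol based
    on Euclidean distances in PC space, Spearman rank tests for allometry with
    removal-based sensitivity analyses, wireframe shape reconstruction along
    PC axes, and a parametric simulator of taphonomically deformed bilaterally
    symmetric skull landmark configurations (dorsoventral and mediolateral
    compression, unilateral crushing, caudal rotation, juvenile allometry)
    with deformation-axis recovery diagnostics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
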