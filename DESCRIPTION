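Package: octtexture
Title: Texture and Thickness Analysis of Retinal Layers in Volumetric OCT
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for quantitative analysis of segmented retinal optical
    coherence tomography (OCT) volumes. Collapses each retinal layer to a
    mean-value fundus (en-face) projection, quantifies its speckle texture
    with a 20-feature grey-level co-occurrence matrix (GLCM) suite
    (Haralick, Conners, Clausi and Soh features), measures per-layer and
    total retinal thickness from segmented interface surfaces, and runs
    longitudinal two-group statistics (baseline-adjusted ANCOVA and
    normality-gated two-sample tests). Includes a synthetic speckle-phantom
    generator that produces full two-group, multi-timepoint cohorts with
    ground-truth boundaries, so every pipeline stage can be validated
    without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
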