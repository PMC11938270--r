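Package: voleconnectome
Title: Directed Weighted Connectome Analysis of the Vole Social Brain
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds and analyses the directed weighted structural connectome
    of the 15-region prairie-vole social brain from retrograde tracer cell
    counts. Covers template-based per-region cell counting on slice images
    (affine label-map fitting, threshold segmentation, ipsi/contra
    attribution), connectome construction from long-format count tables,
    dyad classification, weighted and unweighted hub analysis, module
    detection by hierarchical clustering of projection profiles,
    within-module degree Z-scores and participation coefficients, and
    cartographic node-role classification. Includes a seedable synthetic
    generator for count matrices with planted modular and hub structure and
    for labeled slice images with known per-region cell counts, so the whole
    pipeline is testable without tracer imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    EBImage,
    tiff,
    mclust,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr
Config/testthat/edition: 3
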