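Package: kernelseg
Title: Counting and Measuring Touching Seed Kernels in RGB Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A headless engine for counting and measuring seeds, kernels and
    other small objects photographed on a contrasting background. Pixels of
    interest are extracted by correlation-based principal component analysis
    over the raw RGB channels and twelve derived color indices, followed by
    one-dimensional K-Means classification of the selected component image.
    Touching objects are separated by a divide-and-combine strategy:
    breadth-first-search connected components, marker-controlled watershed
    splitting with a dynamically shrinking marker search region, boundary
    shrinkage for dented rims, and expansion-merging of undersized fragments.
    Per-object area, length and width are measured in pixels and optionally
    converted to millimeters via a reference object of known area. Includes a
    ground-truthed synthetic scene generator and single-image and batch
    processing front ends.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    EBImage,
    jsonlite,
    Rcpp,
    grDevices,
    graphics,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
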