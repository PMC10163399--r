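Package: tcmviz
Title: Similarity-Based Visualization of Traditional Chinese Medicine Formulas
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Joint visualization of traditional Chinese medicine (TCM) formulas
    and the multidimensional pharmacological attributes of their herbs. Formulas
    are read as herb sets with principal-herb (Junyao) flags, herbs are encoded
    as 23-dimensional binary Siqi/Wuwei/Guijing attribute vectors and projected
    to the plane, and a two-step greedy similarity layout arranges formulas as
    icicle-plot columns so that shared herbs align vertically. A shared-herb
    co-occurrence matrix with group summary statistics complements the icicle
    view. Herb colors are derived from anchor colors of representative herbs by
    per-channel linear radial-basis-function interpolation in the CIECAM02-UCS
    perceptually uniform color space, yielding a continuous two-dimensional
    colormap over the embedding. All three views render to deterministic static
    SVG and a combined HTML report; a seeded generator produces synthetic
    formula groups for testing at realistic scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    jsonlite,
    png
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
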