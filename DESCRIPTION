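Package: ClumpSplit
Title: Splitting Overlapping Cells for Quantitative Histology
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Morphology-based cell counting for binary masks of H&E-stained
    tissue in which touching and overlapping nuclei form clumps. Stage one
    discriminates overlapping clumps from single cells using object area,
    diameter equality and convex-hull concavity; stage two splits each clump
    by decomposing its concave deficit regions (splitting triangles) into
    arc and chord, locating critical splitting points by chessboard-distance
    seed growing, pairing nearest points, and cutting along thinned
    shortest-path corridors. Includes a synthetic scene generator with
    per-cell ground truth and precision/recall/F-measure evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    grDevices,
    utils,
    EBImage,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    knitr
Config/testthat/edition: 3
biocViews: CellBiology, Segmentation, Visualization
RoxygenNote: 7.3.3
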