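Package: leukotree
Title: Segmentation, Morphometry and Rule-Based Staging of Myeloid Cells
    in Blood Smear Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for computer-aided staging of myeloid-series white blood
    cells (myeloblast to neutrophil) in stained smear and bone-marrow
    aspirate images. Provides colour-space based whole-cell and nucleus
    segmentation, a small set of morphometric features built around a
    modified bottleneck shape-splitting algorithm (minimum nucleus
    thickness, minimum convex thickness, Hausdorff distance between
    nucleus and cell borders, post-split perimeter), a fixed-threshold
    decision tree assigning each cell to one of eight maturation classes,
    inter-rater agreement metrics (one-vs-rest confusion summaries and
    Cohen's kappa), and a seeded generator of synthetic smear images with
    ground-truth masks for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    grDevices,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
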