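Package: wrinklekit
Title: Quantitative Analysis of Biofilm Wrinkling and Channel Networks Under Flow
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the quantitative study of biofilm wrinkling and hollow
    channel formation in microfluidic devices. Implements the closed-form
    buckling-delamination mechanics of a compressively stressed adherent film
    (critical buckling stress, energy release rate, delamination criterion)
    together with parallel-plate channel hydrodynamics; a wrinkle-network
    quantification pipeline for phase-contrast timelapses (Otsu binarization,
    morphological cleaning, skeletonization, connected-component metrics and
    growth-stage segmentation); differential dynamic microscopy (DDM) with a
    Schulz-swimmer intermediate scattering function fit for bacterial swimming
    speed; spatially resolved image-correlation activity mapping; and
    Owens-Wendt surface free energy estimation from contact angles. Seeded
    synthetic-data generators with machine-readable ground truth make the
    whole pipeline testable without raw microscopy data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tiff,
    jsonlite,
    yaml,
    minpack.lm,
    igraph,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
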