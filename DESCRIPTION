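Package: neuritracer
Title: Automated Neurite Outgrowth Quantification from Two-Channel
    Fluorescence Micrographs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Fully automated, high-throughput quantification of neurite
    outgrowth in calibrated two-channel (nuclear stain / neurite stain)
    16-bit fluorescence micrographs. Binarizes each channel with Phansalkar
    local thresholding, separates clustered nuclei by distance-transform
    watershed, extracts an epsilon-pruned medial-axis skeleton of the
    upscaled neurite mask, subtracts somata, and reports per-image
    morphological metrics (total neurite length, branch points, areas,
    counts). Downstream statistics include normalization to solvent
    control, constrained variable-slope sigmoidal dose-response (LD50)
    fitting and method-comparison linear regression. A synthetic-micrograph
    generator with exact ground truth supports end-to-end validation, and a
    batch pipeline processes whole experiment manifests without manual
    input.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    Rcpp,
    EBImage,
    tiff,
    png,
    minpack.lm,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
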