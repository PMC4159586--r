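Package: scnclust
Title: Spatiotemporal Deconstruction of Circadian Bioluminescence Image Stacks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Automated analysis of bioluminescence image stacks from circadian
    reporter tissue (e.g. PER2::LUC suprachiasmatic nucleus slice cultures).
    The pipeline despikes and coarsens raw movies into superpixel time series,
    clusters them by k-medoids under the cosine distance with gap-statistic
    selection of the number of clusters, computes per-cluster Fourier amplitude
    spectra with white-noise significance lines, applies an 18-30 h band-stop
    (notch) filter to isolate non-circadian structure, and builds a
    correlation-based similarity graph whose normalized-Laplacian spectral
    clustering and two-dimensional spectral embedding yield "clock-face" phase
    readouts and embedding-coherence statistics. A synthetic movie generator
    with wild-type, Cry-null and VPAC2-null phenotype presets provides
    ground-truthed test data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
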