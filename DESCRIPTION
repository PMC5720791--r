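Package: xhclust
Title: Extreme Hierarchical Clustering for Hyperspectral Image Cubes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Unsupervised segmentation of hyperspectral reflectance cubes by
    extreme hierarchical clustering (XHC): a divisive tree decomposition that
    projects the spectra in each node onto the line through two far-apart
    pivot signatures (a FastMap one-dimensional embedding), splits at the
    threshold minimising the within-side variance of the projections, prunes
    the resulting leaves to k representative spectra with Lloyd k-means on
    the leaf means, and assigns every pixel to its nearest representative.
    Includes ENVI-format cube input/output, white/dark reflectance
    calibration, Savitzky-Golay spectral smoothing, band cropping, background
    and overexposure masking, a ground-truthed synthetic wound-scene
    generator, per-cluster pixel quantification inside circular regions of
    interest, and a command-line interface for batch runs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    jsonlite,
    yaml,
    png
Suggests:
    testthat (>= 3.0.0),
    mclust,
    signal,
    withr
Config/testthat/edition: 3
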