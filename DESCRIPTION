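Package: dpcart
Title: Few-View Differential Phase-Contrast CT Reconstruction with Explicit BM3D Filtering
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward modelling and reconstruction for grating-interferometry
    differential phase-contrast computed tomography (DPC-CT). Provides the
    linearly partial-derivative projector for refraction-angle sinograms, a
    Talbot-Lau phase-stepping simulator with attenuation/dark-field/phase
    retrieval, Hilbert-filter filtered backprojection, the differential
    algebraic reconstruction technique (DART) with optional total-variation
    regularization, and an explicit-filtering reconstruction that interleaves
    DART sweeps with BM3D collaborative filtering and frequency-domain
    excitation noise, enabling artifact-free reconstruction from few-view
    scans.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite,
    yaml,
    tiff
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
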