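Package: eida
Title: Eigenvector Decomposition of Instantaneous Phase Alignment
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Lossless closed-form two-eigenvector decomposition of the
    instantaneous phase alignment (iPA) matrix for dynamic functional
    connectivity analysis of parcellated time series. Provides analytic
    (Hilbert) phase extraction with bandpass prefiltering, the exact rank-2
    eigendecomposition of the iPA matrix with degenerate-case handling, a
    discrete pipeline (k-means over losslessly rebuilt matrices in
    upper-triangle space, with dwell times and fractional occurrences), a
    continuous pipeline (position-speed trajectories, functional connectivity
    dynamics matrices, Lempel-Ziv-Welch complexity), a metric suite (spectral
    and Kuramoto metastability, irreducibility index, static functional
    connectivity), and synthetic generators with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    signal,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
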