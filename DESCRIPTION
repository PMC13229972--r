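Package: isodfa
Title: Long-Range Temporal Correlations in EEG via Manifold Embedding and
    Detrended Fluctuation Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies long-range temporal correlations (LRTC) in
    alpha-band EEG dynamics. A cleaned multichannel recording is reduced to
    a windowed alpha-band (8-13 Hz) power feature matrix, embedded in a
    low-dimensional space by Isomap (k-nearest-neighbour graph, geodesic
    distances, classical multidimensional scaling) or by PCA, and the
    scaling exponent alpha of the embedded trajectory is estimated by
    detrended fluctuation analysis (DFA), either on the Euclidean norm of
    the embedding or dimension-wise with averaged exponents.  Includes a
    synthetic-EEG generator driven by exact circulant-embedding fractional
    Gaussian noise, embedding-quality diagnostics (trustworthiness,
    explained variance, elbow selection), moving-block bootstrap confidence
    intervals, paired comparison statistics, and a neighbourhood-size
    sensitivity sweep.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    signal,
    igraph,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
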