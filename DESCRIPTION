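Package: freqlayer
Title: Frequency-Based Multiplex and Multilayer Functional Networks
Version: 0.1.0
Authors@R:
    person("freqlayer", "developers", email = "freqlayer@example.org",
           role = c("aut", "cre"))
Description: Construction and spectral analysis of frequency-based multiplex
    and full multilayer functional networks from multichannel oscillatory
    time series. Band-pass filtering, histogram mutual information,
    block-permutation surrogate thresholding and linear normalization turn
    raw signals into a supra-adjacency matrix whose diagonal blocks are
    frequency-band layers and whose off-diagonal blocks encode
    cross-frequency coupling. The combinatorial supra-Laplacian spectrum
    (algebraic connectivity lambda2, the lambda2-lambda3 transition point
    p*) is analyzed as a function of interlayer weight, weight
    heterogeneity and missing interlayer edges, with Erdos-Renyi and
    Barabasi-Albert ensemble experiments and a synthetic MEG-like signal
    generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
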