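Package: mfpatch
Title: Multifractal Detrended Fluctuation Analysis of Patch-Clamp Current Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Multifractal detrended fluctuation analysis (MFDFA) of single-channel
    patch-clamp current time series. Provides the generalised Hurst exponent H(q),
    the singularity spectrum f(alpha) via the Legendre transform, protocol-aware
    windowing of voltage-step recordings, and replicate aggregation into
    per-condition summary tables. Includes exact synthetic generators with known
    fractal structure (fractional Gaussian noise by circulant embedding, the
    binomial multiplicative cascade, and two-state Markov channel-gating currents)
    so that every stage of the pipeline can be validated against analytic oracles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    graphics,
    jsonlite,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
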