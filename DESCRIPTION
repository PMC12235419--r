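Package: biolumin
Title: Model-Based Analysis of Circadian Bioluminescence Reporter Rhythms
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates and analyses circadian rhythms of luciferase
    bioluminescence reporters whose production rate, degradation rate, or
    luminescence efficiency carries a cosine circadian modulation. Provides
    exact and quadrature oracles for the underlying linear ODE with periodic
    coefficients, a detrending pipeline based on one-period centred moving
    averages (relative values), sub-sample peak/trough refinement, amplitude
    and phase extraction, single-cell intensity statistics (geometric means,
    log-normality testing), and a synthetic-data generator for replicate
    photomultiplier traces and single-cell intensity sets. The rhythm
    properties of stable and unstable luciferases discriminate whether an
    observed bioluminescence rhythm is generated by luciferase amount or by
    luminescence efficiency.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    stats,
    utils,
    nortest
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
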