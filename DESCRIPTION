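Package: synscale
Title: Quantal Synaptic Scaling and Respiratory Motor Output Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for homeostatic synaptic scaling in
    respiratory motoneurons. Detects miniature excitatory postsynaptic
    currents (mEPSCs) in voltage-clamp recordings, applies a fixed
    detection threshold with quality-control filters, and tests for
    multiplicative scaling with the rank-order procedure: equal-count
    rank pairing of control and treated amplitude distributions, linear
    and exponential fits, scaling-factor extraction, threshold-aware
    down-scaling, and Kolmogorov-Smirnov comparison of cumulative
    distributions. Also quantifies intrinsic excitability from
    current-clamp step families (input resistance, firing-rate-current
    gain, ANCOVA slope comparison) and fictive respiratory bursts in
    two-channel integrated neurograms across drug epochs. Ships a
    ground-truth synthetic-data generator (Poisson-timed biexponential
    mEPSC trains, leaky integrate-and-fire step responses, two-channel
    burst neurograms) so every stage is testable against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    signal,
    minpack.lm,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
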