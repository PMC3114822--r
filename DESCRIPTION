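Package: mobilegam
Title: Additive Models with Autoregressive Errors for Mobile-Monitored
    Traffic Pollutants
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Spatio-temporal regression tools for 1-minute mobile-monitoring
    campaigns of traffic-related air pollutants near major roadways. Fits
    penalized additive models of log concentration with smooth
    distance-to-source terms, a bivariate spatial smooth and linear
    meteorology and traffic covariates; refits them under empirically
    selected AR(p) error structures by within-shift whitening; adds
    per-shift smooth time trends; and supports a discretized line-source
    formulation in which every 10-m road segment acts as a traffic-weighted
    individual source. Includes line-source geometry utilities (effective
    distance to elevated roadways, wind-sector classification), covariate
    assembly from raw observation, traffic and weather streams, a synthetic
    campaign generator with documented ground truth, distance-decay curve
    prediction with pointwise confidence intervals, and publication-style
    coefficient tables and smoothed concentration surface maps.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    mgcv,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    ggplot2
Config/testthat/edition: 3
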