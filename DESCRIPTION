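Package: ushrv
Title: Reliability of Ultra-Short-Term Heart Rate Variability Features
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify how reliably heart rate variability (HRV)
    features survive shortening of the analysis window. RR-interval series
    are segmented with sliding windows from 180 s down to 10 s, 31 standard
    HRV features (time, geometric, non-linear and frequency domain) are
    extracted per window placement, and agreement of every short-window
    feature vector with its 180-second reference is summarised through
    Wilcoxon rank-sum acceptance matrices, Spearman correlations aggregated
    with Fisher's z transformation, window-trend linear regressions and
    non-parametric Bland-Altman limits of agreement. A seeded synthetic
    RR-series generator with low- and high-frequency autonomic modulation
    makes the whole pipeline testable without recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    tibble,
    dplyr,
    tidyr,
    rlang,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    ggplot2,
    withr
Config/testthat/edition: 3
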