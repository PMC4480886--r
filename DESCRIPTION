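Package: iprgclight
Title: Simulation and Analysis of Developing ipRGC Light Responses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the light responses of intrinsically
    photosensitive retinal ganglion cells (ipRGCs) across early post-natal
    development. Provides a generative simulator of melanopsin-driven spike
    trains on a multi-electrode array (inhomogeneous Poisson firing driven by
    a latency/adaptation/recovery rate model with subtype-specific irradiance
    sensitivity), extraction of per-response features from spike trains
    (on-latency, peak firing, off-latency, total/initial/steady-state
    spikes), rule-based Type I/II/III electrophysiologic classification,
    recovery and light-adaptation analysis for 1-minute and 1-hour exposure
    protocols, immunohistochemistry density and relative-intensity
    arithmetic, and the accompanying non-parametric statistical comparison
    ladder (Kruskal-Wallis, Mann-Whitney with Bonferroni correction, linear
    mixed models for longitudinal recovery data). All user-facing functions
    take and return tidy data frames so analyses compose with the pipe.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    lme4,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    knitr,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
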