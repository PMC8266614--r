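Package: dwellmix
Title: Truncated Exponential-Mixture Analysis of Single-Molecule Dwell Times
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing single-molecule fluorescence co-localization
    binding kinetics and rifampicin-chase mRNA decay. Simulates binding-event
    dwell times from exponential mixtures under an observation window with
    frame quantization and competing fluorophore photobleaching; calls binding
    events from per-frame intensity traces; fits truncated multi-exponential
    dwell-time distributions to un-binned data by maximum likelihood with
    multi-start optimization and BIC model selection; estimates parameter
    uncertainty by nonparametric bootstrap with error propagation for the
    residual amplitude; compares conditions with two-tailed unpaired tests;
    and estimates mRNA half-lives from reference-normalized decay time courses
    by exponential or linear trendline fits.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
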