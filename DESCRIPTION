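Package: immunocea
Title: Cost-Effectiveness Modelling of Immunotherapy for MSI-H/dMMR Colorectal Cancer
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end, reproducible pipeline for the economic evaluation of
    serplulimab (an anti-PD-1 antibody) against regorafenib in previously treated
    unresectable or metastatic microsatellite instability-high / mismatch-repair
    deficient colorectal cancer. Implements evidence synthesis (pseudo
    individual-patient-data reconstruction from digitized Kaplan-Meier curves,
    unanchored matching-adjusted indirect comparison), survival extrapolation
    (six standard parametric families, a mixture cure model, a general-population
    background-mortality floor), a three-state Markov cohort model on four-week
    cycles, a full cost and utility layer, and an uncertainty suite (one-way and
    probabilistic sensitivity analysis, acceptability curves, scenario analyses).
    A seeded synthetic-cohort generator supplies trial-like inputs so the whole
    pipeline is testable without access to the original patient-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    utils
Suggests:
    flexsurv,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
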