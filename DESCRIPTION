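Package: axonmorph
Title: Axon and Myelin Morphometry with Behavioral and Survival Phenotyping
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Automated morphometry of myelinated axons in stained peripheral
    nerve cross-sections (rolling-ball background correction, Laplacian-of-
    Gaussian candidate splitting, seeded watershed, HSI pixel screening and
    morphological object filters), per-animal endpoints (axon density, lumen
    and myelin sheath areas, g-ratio), behavioral scoring for acoustic
    startle/prepulse inhibition, odor habituation, hot-plate and balance-beam
    assays, densitometric normalization, Kaplan-Meier survival estimation
    with a Gehan-Breslow generalized Wilcoxon test, and factorial/mixed-design
    ANOVA with Tukey HSD post-hocs. Ships ground-truthed synthetic data
    generators (annular nerve images, behavioral sessions, survival cohorts)
    so the full pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    survival,
    MASS,
    mgcv,
    withr,
    jsonlite,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    car,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
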