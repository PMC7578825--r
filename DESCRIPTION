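Package: trophicniche
Title: Trophic Niche, Dietary Overlap and Individual Specialization from
    Gut Contents and Stable Isotopes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantitative tools for fish feeding ecology: diet-composition
    summaries (percent by weight and number), simplified Morisita dietary
    overlap, Roughgarden total niche width (TNW) and its within-individual
    component (WIC), bivariate (d13C, d15N) isotopic niche geometry (Layman
    metrics, convex hull area, standard ellipse area SEA/SEAc, ellipse
    overlap), a Bayesian stable-isotope mixing model with trophic enrichment
    factors, residual permutation and Hotelling's T-squared tests for niche
    location and dispersion, and random-intercept mixed models with
    likelihood-ratio tests for diel feeding rhythm. Includes seeded
    synthetic-data generators for every input table so the full pipeline is
    testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    MASS,
    lme4,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
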