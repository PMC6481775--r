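Package: allohet
Title: Predicting Heterosis from Nonlinear Allometric Relationships
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools to quantify and predict heterosis (hybrid vigour) in
    plants from the curvature of allometric relationships. Fits nonlinear
    allometries of growth rate (power law with mass-corrected exponent)
    and fruit number (inverse quadratic) against vegetative dry mass,
    together with standardized major axis regression on the log-log
    scale and logistic growth-curve fits. Measures mid-parent and
    best-parent heterosis per hybrid, classifies hybrids by a bootstrap
    comparison with parental values, estimates broad-sense heritability,
    and predicts heterosis from parental masses alone via the nonlinear
    deviation (NLDev) of the accession-fitted allometry. Includes
    pairwise genetic, geographic and phenotypic distance baselines and a
    synthetic-data generator emulating a replicated accession/hybrid
    phenotyping design with spatially structured SNP matrices.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    minpack.lm,
    lme4,
    geosphere,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
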