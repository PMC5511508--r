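Package: cardiogrowth
Title: Postnatal Cardiac Growth, Centile Standards and Ventricular Shape
    Analysis for Preterm-Born Infants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study disproportionate postnatal cardiac hypertrophy in
    infants born preterm. Provides a calibrated synthetic-cohort generator
    (two birth groups, longitudinal fetal and postnatal echocardiography,
    parametric four-chamber ventricular contours), deterministic
    echocardiographic derivations (Boyd body surface area, linear and
    area-length ventricular mass and volume, functional indices),
    fractional-polynomial growth centiles and z-scores for cardiac mass
    against postmenstrual age, a two-dimensional point-distribution shape
    model with linear-discriminant morphological signature discovery under
    leave-one-out cross-validation, and the cohort comparison and regression
    statistics layer, together with an end-to-end reproducible pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tibble,
    utils
Suggests:
    lme4,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
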