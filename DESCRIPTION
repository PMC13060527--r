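Package: alcgwis
Title: Genome-Wide Gene-Alcohol Interaction Analysis of Blood Pressure
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for genome-wide gene-environment interaction studies
    (GWIS) of blood pressure with alcohol consumption as the exposure.
    Implements cohort-level joint main-plus-interaction regression with the
    one-degree-of-freedom interaction and two-degree-of-freedom joint Wald
    tests, phenotype harmonization (antihypertensive medication adjustment,
    pulse pressure, winsorization, standard-drink conversion, exposure
    contrasts), variant and cohort quality control with genomic control,
    inverse-variance-weighted and inverse-covariance-weighted fixed-effects
    meta-analysis within and across populations, and a tiered discovery
    framework with LD clumping, effective-number-of-tests correction,
    novelty classification, sex and population heterogeneity screens, and
    exposure-stratified effect decomposition.  A synthetic cohort generator
    produces individual-level data under the same interaction model so the
    whole pipeline can be exercised and calibrated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, tools, yaml, jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
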