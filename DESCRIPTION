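Package: albunemia
Title: Multi-Cohort Biomarker Axis Discovery, Replication and Clinical Scoring
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for extracting latent physiological axes from panels of
    routine clinical biomarkers measured in multiple aging cohorts. Implements
    the per-cohort transformation and standardization protocol (skewness-guided
    log/sqrt transforms, sex-stratified estradiol), principal-axis extraction
    with loading-importance profiles, cross-population and random-exclusive-
    subset replication with a resampling stability null, quadratic mixed-model
    age trajectories, an association suite for mortality (Cox regression with
    age as the timescale), frailty and comorbidity counts, and chronic-disease
    flags, and a reduced 14-marker clinical composite score. A synthetic
    multi-cohort generator with known two-factor structure, age dynamics,
    missingness and factor-linked outcomes makes every stage testable without
    restricted cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    splines,
    survival,
    nlme,
    lme4,
    MASS,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
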