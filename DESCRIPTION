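Package: alphaband
Title: Individualized EEG Alpha-Band Anchoring and the Alpha3/Alpha2
    Prognostic Ratio
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Computes resting-state EEG biomarkers anchored to
    subject-specific frequency landmarks: the theta/alpha transition
    frequency (TF) and the individual alpha frequency (IAF) peak are
    detected on a channel-averaged ("collapsed") Welch power spectrum,
    subject-specific band edges are derived from them, and relative band
    powers together with the alpha3/alpha2 and theta/gamma power ratios
    are computed as prognostic markers for conversion from mild cognitive
    impairment to Alzheimer's disease. Includes the preprocessing contract
    (common-average re-referencing, 2-s epoching, threshold-based artifact
    rejection), a cohort statistics layer (Levene-gated ANOVA/ANCOVA with
    Games-Howell or Bonferroni post-hocs, Pearson correlations, chi-square
    tests, stepwise canonical discriminant analysis), readers and writers
    for EDF recordings and delimited cohort tables, and a synthetic
    EEG/cohort generator so that every stage is testable without patient
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    MASS
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
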