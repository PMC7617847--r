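Package: painconn
Title: Developmental Analysis of Pain-Connectome Functional Connectivity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to characterise the maturation of resting-state functional
    connectivity within the brain's pain connectome, from neonatal BOLD fMRI to
    adult-normalised connection strengths. The package extracts gray-matter ROI
    mean time series from labelled 4D volumes, estimates absolute Pearson
    partial correlations between 12 bilateral pain-related regions (66
    hemisphere-averaged connections), screens spurious values with Cook's
    distance (infants, against the postmenstrual-age trend) and a 3-SD rule
    (adults), normalises infant connection strengths by adult means, calls
    connection presence against a thalamus-SI reference in the youngest
    infants, and runs the maturation statistics battery: linear regressions on
    postmenstrual age, Dunnett-corrected group-versus-adult comparisons,
    age-by-subnetwork two-way ANOVA with Tukey pairwise tests, and
    FDR-corrected per-connection t-tests. A synthetic-cohort generator with
    age-dependent partial-correlation growth curves makes the full pipeline
    testable without access to the source imaging cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    tibble,
    dplyr,
    tidyr,
    rlang,
    RNifti,
    jsonlite,
    yaml,
    multcomp,
    emmeans,
    car
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
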