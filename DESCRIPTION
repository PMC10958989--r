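Package: demtrend
Title: Dementia Incidence Trends and Burden Projection from Ageing Panel Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating calendar-time trends in dementia incidence from
    longitudinal ageing-panel data and projecting future dementia burden. Implements an
    algorithmic dementia case definition (education-stratified cognitive thresholds,
    transient-decline exclusion, informant questionnaire and functional-impairment rules),
    overlapping 4-year subcohort incidence with direct age-sex standardisation,
    restricted-cubic-spline Cox trend models with cluster-robust variance, a three-state
    illness-death hidden Markov model with misclassification that corrects the bias from
    dementia cases dying between panel waves, a two-dimensional P-spline mortality
    forecaster, and a ten-state Markov cohort model projecting dementia burden under
    incidence and mortality scenarios. A seeded synthetic ageing-panel generator with a
    latent three-state process supports testing and simulation studies end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    splines,
    survival,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    Matrix,
    jsonlite
Config/testthat/edition: 3
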