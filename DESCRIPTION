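Package: anestheeg
Title: Age-Dependent Propofol EEG Band Power and Burst Suppression Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for frontal electroencephalogram (EEG)
    recordings acquired during propofol anesthesia in pediatric cohorts
    (autism spectrum disorder versus neurotypical). Provides multitaper
    spectral estimation with discrete prolate spheroidal sequence (DPSS)
    tapers, anesthesia-log driven selection of stable 120-second analysis
    epochs, age-varying median cohort spectrograms, Bayesian linear
    regression of alpha (8-13 Hz) and slow (0.1-1 Hz) oscillation power on
    cubic age with group interactions (Gibbs sampling, highest posterior
    density intervals), burst-suppression event detection and case grading,
    Beta-posterior comparison of cohort suppression incidences,
    standardized mean difference cohort tables, a calibrated synthetic
    cohort generator, and minimal EDF input/output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    signal,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
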