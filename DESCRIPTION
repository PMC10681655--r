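Package: fcgrad
Title: Functional Connectivity Gradients, Test-Retest Reliability, and
    Behavior Associations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for deriving the principal functional connectivity (FC)
    gradient of the cerebral cortex from parcellated fMRI time series and for
    evaluating its measurement properties. Implements time-series cleaning
    (nuisance and finite-impulse-response task-signal regression, spectral
    filtering, and motion censoring in a single projection), resting-state and
    general functional connectivity (rsFC/GFC) assembly with controlled data
    amounts, diffusion map embedding of sparsified connectomes with Procrustes
    alignment to a group template, the unimodal-to-heteromodal gradient range,
    ICC(3,1) test-retest reliability for edges, thresholded edges, regional
    gradient values and gradient range (including scan-length sweeps), and
    mass-univariate behavior associations with standardized OLS and
    Benjamini-Hochberg FDR correction. A synthetic test-retest cohort
    generator plants a known cortical hierarchy and behavior couplings so the
    full pipeline can be validated end to end without restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
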