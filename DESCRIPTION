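Package: coupleEEG
Title: Trial-Level Brain-Behavior Coupling Analysis for EEG
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for relating single-trial EEG source activity to
    trial-by-trial behavior. Implements sensor-space conditioning
    (zero-phase Butterworth filtering, common-average re-referencing,
    epoch segmentation, baseline correction, amplitude-based trial
    rejection), linearly constrained minimum variance (LCMV) beamforming
    to three-dipole region-of-interest time courses, mass-univariate
    robust regression of behavior on source amplitude, one-sample
    Hotelling T-squared group statistics with sign-flip max-cluster
    permutation inference, and the accompanying behavioral statistics
    (within-group Z-transforms, robust slopes, repeated-measures ANOVA,
    Newman-Keuls post-hoc tests, JZS default-prior Bayes factors, and
    Fisher-z accuracy correlations). A synthetic-data module generates
    behavioral trial tables and sensor epochs with known ground-truth
    coupling so that every stage of the pipeline can be validated
    end-to-end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    signal,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    MASS,
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
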