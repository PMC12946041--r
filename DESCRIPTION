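Package: spnlab
Title: Symmetry ERP Analysis: Sustained Posterior Negativity Pipeline
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested, reusable pipeline for brief-exposure visual symmetry
    EEG experiments. Generates mirror-symmetric and asymmetric octagon
    stimuli, simulates behavior from an equal-variance signal-detection
    model and epoched multi-channel EEG with 1/f noise plus an injected
    sustained posterior negativity (SPN), screens epochs with automated
    amplitude/trend/kurtosis criteria, performs spatiotemporal cluster-based
    permutation testing over an electrode neighbor graph, quantifies the
    SPN in cluster-derived and canonical posterior regions of interest,
    computes signal-detection and lateralization statistics, and estimates
    trial-count reliability by fixed-cohort subsampling with exact
    Clopper-Pearson intervals.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    jsonlite,
    yaml,
    ggplot2,
    generics
Suggests:
    testthat (>= 3.0.0),
    e1071,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
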