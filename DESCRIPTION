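Package: fcmodes
Title: Static and Time-Varying Functional Connectivity Modes of Behavior
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for relating resting-state functional connectivity to
    behavior through two complementary arms: static edgewise correlation
    connectivity, and time-varying connectivity summarized by a Gaussian
    observation hidden Markov model (HMM). Includes a ground-truth-known
    synthetic data generator for multi-subject, multi-session node time
    series with planted state dynamics and behavioral factor structure;
    confound regression, bandpass filtering and framewise-displacement
    quality control; fractional occupancy, switching rate and metastate
    summaries of HMM state time courses; maximum-likelihood factor analysis
    of behavioral batteries with promax rotation; and canonical correlation
    analysis with subject-grouped permutation inference, grouped
    cross-validation and post hoc loadings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    signal,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
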