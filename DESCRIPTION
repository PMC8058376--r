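Package: qeegstroke
Title: Quantitative EEG Monitoring of Experimental Cerebral Ischemia and Reperfusion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for continuous quantitative EEG (qEEG) monitoring
    of focal cerebral ischemia and reperfusion in the rodent middle cerebral
    artery occlusion (MCAO) model. Reads and writes single-channel
    electrocorticography recordings (European Data Format or delimited text),
    conditions them (zero-phase high-pass filtering, epoching, amplitude-based
    artifact rejection), estimates Welch power spectral densities, and computes
    relative band power in the canonical delta, theta, alpha and beta bands up
    to a 40 Hz analysis ceiling. From the band powers it derives the
    delta/theta (DTR), delta/alpha (DAR) and (delta+theta)/(alpha+beta) (DTABR)
    stroke-severity indices and classifies ischemic state against published
    thresholds. Includes a calibrated synthetic-cohort generator (band-limited
    Gaussian noise matched to target spectral profiles), the study's
    statistical battery (Kolmogorov-Smirnov normality with Lilliefors
    Monte-Carlo calibration, Student's t, one- and two-way ANOVA, Tukey HSD
    with compact letter display), and percentage-infarct-area quantification
    from binary lesion masks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    png,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    nortest,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
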