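Package: srtsim
Title: Simulation of Speech-on-Speech Masking Experiments with Adaptive
    SRT Staircases and Glimpsing Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools to simulate closed-set matrix sentence speech-recognition
    experiments in competing speech. Provides a deterministic parametric
    synthesizer for a matrix word corpus (five categories by ten monosyllabic
    words for one target and four masker talkers), sentence assembly with
    per-word time reversal and pitch-preserving duration matching, mixing of
    target and multi-talker maskers at commanded signal-to-noise ratios, a
    volume-unit-meter style glimpsing analysis (sliding long-term RMS, glimpse
    proportion and mean glimpsing signal-to-noise ratio), psychometric
    simulated listeners, the one-up one-down adaptive speech recognition
    threshold staircase with last-six-reversal scoring and run validity rules,
    and derived masking-release and multi-masker-penalty contrasts in both
    SNR and target-to-masker-ratio accounting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
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
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
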