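Package: sleeptopo
Title: Topographic Wake and Sleep EEG Analysis for Cognitive Decline Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the joint analysis of wake and sleep
    electroencephalography in clinical cohorts (Alzheimer's disease, mild
    cognitive impairment, healthy controls). Scores sleep macrostructure from
    staged hypnograms, estimates Welch band-power topographies over the 19
    channel 10-20 montage, runs channel-wise one-way ANOVA and t-test maps
    with Benjamini-Hochberg false discovery rate control, computes the EEG
    slowing index (delta + theta) / (alpha + sigma + beta) and the overnight
    change in waking delta power, and links these indices across behavioral
    states and to cognition via Pearson/Spearman correlation topographies and
    Fisher-z linear trends. Includes a seeded synthetic-cohort generator so
    the full pipeline can be exercised and validated without patient data,
    plus summary-statistics ANOVA and t tests for recomputing inferential
    results from published group means and standard deviations.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
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
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
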