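Package: heinvs
Title: Healthy Eating Index-NVS Scoring and Longitudinal Trial Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Scores seven-day food diaries with the Healthy Eating
    Index-NVS, the German diet-quality index built on the reference
    amounts of the German Nutrition Society (10 food-group components,
    110 points), and runs the longitudinal analysis of a two-arm
    web-based weight-loss trial on the resulting scores: multiple
    imputation by chained equations with Rubin's-rules pooling, a
    Huber-weighted robust linear mixed model of the time-by-group
    course, within-group standardized change effect sizes, and
    bias-corrected bootstrapped Pearson correlations between change in
    diet quality and change in dietary, anthropometric and
    cardiometabolic variables. A synthetic-trial generator emulating
    the trial's design (permuted-block randomization, monotone
    dropout, configurable change-score correlations) makes every stage
    runnable end-to-end without access to the original data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    boot,
    jsonlite,
    lme4,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
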