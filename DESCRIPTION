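Package: riskimagery
Title: Affect-Laden Mental Imagery and Risk Taking: Mediation, Psychophysiology
    and Moderation Analyses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how affect-laden mental imagery relates to risk
    perception and risk taking. Implements serial two-mediator path models
    estimated with crossed random-intercept linear mixed models and Monte-Carlo
    confidence intervals for the three-path indirect effect; the mean-arterial-
    pressure (MAP) reduction pipeline for cuff blood-pressure stress reactivity;
    EEG alpha-band (8-13 Hz) power and the Imagery Alpha Index (IAI), a relative
    task/baseline alpha measure of imagery intensity; repeated-measures ANOVA
    with Greenhouse-Geisser correction, Holm post-hocs, intraclass correlations
    and PANAS change analyses; and Johnson-Neyman probing of moderated mixed
    models. Ships deterministic synthetic-data generators that emulate the three
    study designs with known ground truth, so every pipeline stage is testable
    end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    car,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    lme4,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
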