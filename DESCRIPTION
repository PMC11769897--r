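Package: effortdm
Title: Effort-Based Decision Making with Intrinsic and Extrinsic Control
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation and analysis of an effort-based decision-making task
    in which effort is either offered externally (extrinsic control:
    accept/reject an offered number of button presses for an offered outcome)
    or set by the participant (intrinsic control: self-generated effort for an
    offered outcome), across win/loss valence and monetary/social outcomes.
    Provides a task-schedule builder, three effort-by-outcome discount curve
    families (linear, sigmoid, Weibull) with choice and report likelihoods,
    a synthetic-cohort generator with clinical-group and symptom structure,
    hierarchical empirical-Bayes curve fitting with Laplace model evidence,
    random-effects Bayesian model selection with protected exceedance
    probability, and the parameter-level group statistics (repeated-measures
    ANOVA, Tukey post-hoc, covariate-adjusted partial correlations,
    dependent-correlation Z tests, Cronbach's alpha, paired t tests).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
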