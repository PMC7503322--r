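Package: shuttlebox
Title: Simulation and Analysis of Stressor-Controllability Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to run and analyse the triadic stressor-controllability
    paradigm in silico. Provides trial engines for escapable, yoked
    inescapable, and no-stress control conditions (including one-to-one
    yoking and pseudo-yoking of stress schedules), a grid-based escape
    behaviour test translated from the animal shuttle-box task, generative
    models of simulated participants (reaction times, trial-and-error
    cue-button learning, navigation policies, Likert ratings, affect
    scores), the paradigm's behavioural read-outs (exploration, escapes,
    efficiency, reaction time, correct-response rate), and its statistical
    pipeline (extreme-outlier exclusion, chi-square, summary-statistic
    t-tests and one-way ANOVA, Kruskal-Wallis with eta-squared-H, mixed
    repeated-measures ANOVA with Greenhouse-Geisser correction, Holm and
    Bonferroni multiplicity control). All simulations are deterministic
    given a seed and every record round-trips through plain CSV logs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    car,
    withr,
    jsonlite
Config/testthat/edition: 3
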