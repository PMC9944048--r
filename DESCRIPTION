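Package: forageBandit
Title: Epsilon-Greedy Bandit Models of Cortisol-Modulated Fish Foraging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models animal foraging in a four-arm maze as a k-armed bandit
    solved by the epsilon-greedy algorithm, with each individual's exploration
    rate set to its min-max-normalized basal cortisol level. Provides the
    bandit environment and sample-average learner, an exact dynamic-programming
    oracle for expected rewards, cohort ingestion with validity filtering and
    ordered cortisol grouping, a synthetic-cohort generator, cohort-scale
    digital-twin simulation with group mean/standard-error summaries and
    cumulative-reward trajectories, and fish-versus-simulation correlation
    reports. The central interface is bandit_twin(), a fitting function
    returning a classed object with the usual print, summary, predict, plot,
    simulate and residuals methods.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
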