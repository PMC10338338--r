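Package: clockrace
Title: Competing-Clocks Analysis of Cell-Cycle Commitment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of cell-cycle commitment as a temporal
    competition between two single-cell clocks: the time from mitogen
    withdrawal to mitosis and the time to lose CDK2 activity and exit the
    cell cycle. Generates synthetic live-cell CDK2/APC(C) reporter traces
    under cell-line presets and treatment programs, extracts S-phase entry,
    mitosis and exit landmarks, fits exit-probability logistic models, runs
    the Monte Carlo clock race with an analytic oracle, models cyclin A2
    mRNA shutoff and protein decay (the kinetic exit clock), and contrasts
    feedback and feed-forward ODE architectures of the mitogen-to-CDK2
    pathway (bistability, hysteresis, dose-response).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
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
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
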