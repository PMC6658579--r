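Package: fitloop
Title: Simulation of Fitness Estimation, Feedback Inversion and Two-Stage Loops
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the computational theory of an organism's internal
    estimate of its own evolutionary fitness: a drifting world with a
    multi-peak fitness landscape, a bank of slowly nonstationary estimator
    operators, approximate inversion of those operators by a high-gain
    feedback loop, a switched two-stage loop with sample-and-hold buffers,
    sender-receiver dialogue over a noisy channel, and a variance-modulated
    stochastic drive in which the fitness estimate controls the magnitude
    (not the direction) of random changes of the organism's form. Provides
    tidy trace tables, estimator- and inversion-quality metrics, scenario
    configuration files, canonical fixtures, and paired permutation tests
    for the mechanism's fitness benefit.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
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
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
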