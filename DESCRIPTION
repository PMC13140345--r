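Package: hutsim
Title: Hypogravity Simulation with Head-Up-Tilt Body Suspension
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Physics and analysis toolkit for whole-body suspension
    hypogravity analogues that tilt a rope-suspended body head-up so a
    fraction of Earth's gravity acts along the body axis. Maps tilt angle
    to simulated gravity level, plans per-rope lengths and counterbalance
    loads from anthropometric body-segment fractions, models the
    pendulum-effect error that inflates axial acceleration during dynamic
    movement (with a ballistic jump-apex integrator), processes
    force-platform recordings into percent-bodyweight loading, and runs
    validity and reliability analytics (error summaries, Bland-Altman
    agreement with confidence intervals, two-way absolute-agreement
    intraclass correlation). Ships condition-level and per-participant
    validation tables from a proof-of-concept suspension campaign and
    seeded synthetic generators with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    withr
Suggests:
    jsonlite,
    lme4,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
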