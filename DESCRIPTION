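Package: eimtd
Title: Early Identification of the Maximum Tolerated Dose in
    Time-to-Event Model-Assisted Dose-Finding Designs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for phase I oncology dose-finding with the mTPI,
    Keyboard, and Bayesian optimal interval (BOIN) model-assisted designs
    and their time-to-event (TITE) extensions.  Builds escalation and
    de-escalation decision-boundary tables, computes the beta-binomial
    dose-retainment probability that supports early declaration of the
    maximum tolerated dose (MTD) from an interim trial state with pending
    safety assessments, and simulates complete trials to estimate
    operating characteristics: correct-selection rate, early-identification
    rate, study duration, and sample size.  Functions are tibble-first and
    pipe-friendly, with broom-style tidiers and ggplot2 autoplot methods.
License: MIT + file LICENSE
Encoding: UTF-8
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
    tidyr
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
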