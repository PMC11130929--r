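Package: msmnet
Title: Partnership Duration and Homophily Estimation for MSM Sexual Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Estimates sexual partnership durations and activity-group
    homophily among men who have sex with men (MSM) from behavioural survey
    summaries. Provides a synthetic survey generator emulating categorical
    12-month partner counts, an iterative algorithm reconstructing integer
    counts from interval-censored categories, a discrete-time simulator of
    three overlapping partnership networks (steady, persistent casual,
    one-off) with target-driven formation and constant-hazard dissolution,
    closed-form homophily balance between activity groups, and adaptive
    ABC-SMC (population Monte Carlo) calibration of duration and homophily
    parameters against cumulative-partner summary statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ggplot2,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
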