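Package: valseq
Title: Value-Based Bayesian Sequential Clinical Trial Design
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Design and evaluation of value-based Bayesian sequential
    clinical trials with delayed outcome observation. Solves the optimal
    stopping problem for a conjugate-normal belief about expected
    incremental net monetary benefit by backward induction, classifies the
    optimal design (no trial, one-stage, sequential) from the prior mean,
    replays block-level trial data against the stopping boundary with
    scheduled interim analyses and pipeline follow-up, and computes
    operating characteristics by bootstrap and Monte Carlo resampling.
    Includes a synthetic-data generator emulating a two-arm pragmatic
    trial of surgery versus sling immobilisation for displaced proximal
    humeral fracture.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
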