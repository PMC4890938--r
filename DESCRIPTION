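Package: carryprev
Title: Contamination-Aware Drug Prevalence from Sequential Anonymous Urine Samples
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the prevalence of drug use from anonymous urine samples
    drawn sequentially by an automated multi-container sampler, where residual
    liquid in the intake tubing can carry part of one sample's drug content
    into the next. Implements the conservative sequential classification rule
    that labels a detection 'contaminated' when its concentration does not
    exceed the previous sample's measurement, the contamination-adjusted
    prevalence statistic with large-sample normal-approximation confidence
    intervals, drug-combination and concentration summaries, and a-priori
    precision calculations for a single proportion. A synthetic event
    simulator emulates the sampler (cassettes of 24 slots, residual-volume
    carryover, per-substance detection limits, repeat visitors) so the
    estimator's conservative bias and confidence-interval coverage can be
    quantified by Monte-Carlo experiment.
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
    stats,
    tibble,
    tidyr,
    tools,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
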