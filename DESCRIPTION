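Package: markovcea
Title: Markov Cohort Cost-Utility Modelling for Cardiovascular Prevention Programs
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: A discrete-time Markov cohort framework for cost-utility analysis
    of community wellness programs that modify cardiovascular risk factors.
    Converts multi-year Framingham-style risk estimates into annual transition
    probabilities over a five-state model (healthy, stroke, myocardial
    infarction, congestive heart failure, death), runs the cohort simulation
    with configurable discounting and reward-timing conventions, accumulates
    discounted quality-adjusted life years and life years, builds program cost
    schedules from line items with fringe and indirect loading, and reports
    incremental cost-effectiveness ratios for intervention versus
    counterfactual scenarios. Includes a synthetic health-assessment cohort
    generator stratified by sex and diabetes status so the full pipeline is
    reproducible without access to restricted participant data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
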