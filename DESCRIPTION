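Package: trdcea
Title: Markov Cohort Cost-Utility Model for Treatment-Resistant Depression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discrete-time Markov cohort state-transition model comparing
    electroconvulsive therapy (with and without maintenance ECT) against
    intranasal esketamine for treatment-resistant depression. Implements
    rate/probability conversion for deriving per-cycle transition
    probabilities from trial summaries, societal and healthcare costing with
    a human-capital productivity-loss formula, tunnel states for
    maintenance-treatment phases, discounted QALY and cost accounting,
    incremental cost-effectiveness (ICER and dominance) with NICE threshold
    classification, a deterministic sensitivity-analysis scenario runner,
    and an individual-level microsimulation oracle plus synthetic trial
    generator for validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
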