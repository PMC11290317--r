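Package: selbias
Title: Selection-Bias Testing of Randomized Trials via Baseline I2 Meta-Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a statistical test for selection-bias risk in a single
    randomized controlled trial (RCT). The trial's baseline summary (mean, SD,
    N per arm) is pooled with two simulated comparator trials (SCTs) - balanced
    two-arm pseudo-trials built from block-randomized, sorted uniform random
    integers - in a fixed-effect inverse-variance meta-analysis; an I2 point
    estimate above 0% flags the trial as being at high risk of selection bias.
    Includes converters from commonly reported summaries (mean/SE, median with
    min-max range or interquartile range) to mean/SD form, diagnostic-accuracy
    statistics (false omission rate and negative likelihood ratio with 95%
    confidence intervals) for auditing risk-of-bias ratings against test
    results, a synthetic trial-cohort generator with controllable arm
    misallocation, and CSV/JSON input-output for cohort tables and reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    metafor,
    withr,
    optparse
Config/testthat/edition: 3
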