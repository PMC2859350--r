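Package: tdiagree
Title: Total Deviation Index with Tolerance-Interval Inference for
    Method Comparison Studies
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Agreement analysis for two measurement devices with replicated
    readings. Estimates the total deviation index (TDI) as a probability
    interval of the paired-difference distribution (solved by a modified
    binary search), with exact one-sided tolerance-interval inference based
    on the non-central Student-t distribution, intra-, inter- and total-method
    variants, coverage-probability bounds, variance-component estimation for
    balanced repeated-measures designs, comparator upper bounds (MSD/GEE and
    maximum-likelihood plug-in), and a Monte-Carlo harness for evaluating
    empirical confidence of the bounds.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    lme4,
    pracma
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
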