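Package: wcmr
Title: Winner's-Curse-Corrected Two-Sample Summary-Data Mendelian Randomization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Corrects the winner's curse in two-sample summary-data Mendelian
    randomization when the instrument SNP is selected from the exposure GWAS
    at a significance threshold. Models the selected exposure effect estimate
    by a two-tail truncated (conditional) normal distribution, computes the
    conditional maximum-likelihood estimate of the SNP-exposure effect by
    solving the score equation, and reports the corrected causal-effect
    estimate, the conditional likelihood-ratio test of no causal effect, and a
    k-unit profile-likelihood support interval with multiple-testing
    calibration of k. The classical SMR ratio estimator with its delta-method
    variance and Wald interval is provided for comparison, together with a
    Monte-Carlo engine for coverage and power studies and a validation module
    for the equivalence of the delta-method variance and the two-stage
    least-squares variance on one-sample individual-level data.
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
    optparse
Config/testthat/edition: 3
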