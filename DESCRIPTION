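Package: scepticalRWE
Title: Replication Success of Randomized Trials in Real-World Evidence Emulations
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Statistical assessment of replication success for pairs of a
    randomized controlled trial (RCT) and its real-world evidence (RWE)
    emulation on the log hazard-ratio scale. Implements the reverse-Bayes
    sceptical p-value with support for non-inferiority margins, its exact
    Type-I-error-controlled recalibration, one-sided confidence intervals by
    test inversion, conditional and predictive replication power, the
    two-trials rule and a fixed-effect meta-analytic comparator. Ships the
    summary statistics of the 29 RCT DUPLICATE study pairs as a fixture and a
    pipeline that reproduces the published replication-success counts, plus a
    Monte-Carlo simulation harness to verify Type-I error and power.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils
Suggests: testthat (>= 3.0.0), withr, jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
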