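Package: stopsignal
Title: Simulation and Consensus Analysis of Stop-Signal Task Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for the stop-signal task built on the independent race
    model. Simulates trial-level sessions with ex-Gaussian go and stop
    finishing times, an adaptive stop-signal-delay staircase, trigger
    failures and go failures; estimates stop-signal reaction time (SSRT)
    with the consensus non-parametric methods (integration with replacement
    of go omissions, and the mean method); enforces the consensus validity
    and exclusion rules (race-model independence check, p(respond|signal)
    range, go-omission rate); produces the consensus descriptive report per
    group and condition; and runs factorial Monte-Carlo studies of
    estimator bias and reliability as well as group-level power analyses
    for planning sample and trial numbers.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
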