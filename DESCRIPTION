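Package: aerisk
Title: Adverse Event Risk Estimation Under Competing Events and Censoring
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: One-sample estimators of the cumulative adverse event (AE)
    probability in clinical trials with varying follow-up times, competing
    events and censoring: incidence proportion, incidence densities and
    their probability transforms, one minus Kaplan-Meier, and the
    Aalen-Johansen estimator (all-competing-event and death-only variants).
    Includes SmPC frequency categorisation, bootstrap comparison of
    estimators against the Aalen-Johansen gold standard on the ratio
    scale, random-effects meta-analysis and meta-regression of log-ratios
    across many (trial, AE-type) units, and a competing-risks trial
    simulator with known truth for validating the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    metafor,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    survival,
    cmprsk,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
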