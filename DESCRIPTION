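Package: dxestimand
Title: Estimands and Interfering-Event Strategies for Diagnostic Accuracy Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Declarative estimands for diagnostic test accuracy studies:
    a five-attribute estimand specification (population, target condition,
    index test, accuracy measures, per-event handling strategies) applied to
    subject-level study records or stratified count tables. Implements six
    strategies for interfering events (diagnostic policy, indicative event,
    setback, hypothetical, while-under-monitoring, principal stratum),
    accuracy measures with Wilson or Clopper-Pearson confidence intervals,
    a comparative-design layer with bootstrap contrasts, and a synthetic
    study simulator with disease-state-dependent event mechanisms and full
    counterfactual fields.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    withr
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
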