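Package: aoe
Title: Retrospective Adjudication of Arterial Occlusive Events in Clinical Trials
Version: 0.1.0
Authors@R:
    person("Adjudication", "Tools", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A reusable pipeline for retrospective, committee-style
    adjudication of arterial occlusive events (AOEs) in clinical trial
    safety databases. Provides MedDRA preferred-term screening of adverse
    event records, 48-hour clustering of records into candidate clinical
    events, a deterministic rule engine encoding charter definitions for
    cardiovascular endpoints (myocardial infarction types 1/2/4a/4b/4c/5,
    heart failure events, hospitalization for unstable angina, stroke
    subtypes, venous thromboembolism, peripheral vascular disease, and
    cause-of-death categories), a multi-reviewer consensus workflow with
    escalation to a third reviewer and specialty panels, exposure-adjusted
    incidence and risk-factor analytics, and a seeded synthetic-trial
    generator plus a calibrated 449-patient fixture for end-to-end testing
    without any external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
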