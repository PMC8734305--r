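# aoe — retrospective adjudication of arterial occlusive events

Safety tables in oncology trials code adverse events as MedDRA preferred
terms, and naive preferred-term counts overstate arterial occlusive event
(AOE) risk: symptoms, investigations and presumptive diagnoses all match
vascular-sounding terms. The accepted correction is independent committee
adjudication against charter-defined cardiovascular endpoint definitions.
`aoe` implements that process as a deterministic, fully tested R pipeline
for trial biostatisticians and pharmacovigilance analysts:

* **Screen** — exact matching of normalized preferred terms against a
  packaged 604-term AOE list plus a heart-failure term set; chair review of
  deaths not attributed to disease progression.
* **Group** — a patient's flagged records whose onsets chain within 48 h
  form one candidate clinical event (connected components of the pairwise
  gap graph).
* **Adjudicate** — a rule engine encodes the charter definitions
  (MI types 1/2/4a/4b/4c/5 per the universal MI definition, heart-failure
  hospitalization/urgent visit with AOE attribution, hospitalization for
  unstable angina, stroke subtypes, SVT/DVT/PE, peripheral vascular
  disease, and cause-of-death categories) over tri-state evidence
  (known / known-absent / unknown), emitting a criterion-level trace;
  a committee model adds two-reviewer voting, third-cardiologist
  escalation, specialty panels and fatal-event consensus.
* **Analyze** — patient-level rates with half-away-from-zero percent
  rounding, exposure-adjusted incidence
  (first events in interval / patient-years at risk × 100, later intervals
  excluding prior-event patients), time to onset in months (days/30.4375),
  risk-factor strata (0, 1–2, ≥3 of six factors), relative risk with
  log-normal CI, dose-modification and resolution summaries.
* **Simulate** — a seeded generator with per-patient hazard
  `baseline · ∏(factor effects) · decay^⌊t⌋`, plus a calibrated
  449-patient fixture whose published marginals are reproduced by running
  the real pipeline, not by hard-coded outputs.

## Worked example

```r
library(aoe)

ds <- build_paper_calibrated_fixture()   # deterministic 449-patient trial
ds
#> <aoe study dataset>
#>   patients:       449
#>   AE records:     12224
#>   deaths:         50
#>   evidence keys:  490

pl <- aoe_pipeline(ds)                   # screen -> group -> adjudicate
pl$screen$totals
#> records_screened  records_flagged patients_flagged     fatal_review
#>            12224              455              181               45

dt <- pl$outcomes_dt
patient_level_rates(dt, ds$patients)
#> adjudicated/any: 78/449 (17%)
patient_level_rates(dt, ds$patients, records = ds$adverse_events,
                    source = "nonadjudicated")
#> nonadjudicated/any: 111/449 (25%)
patient_level_rates(dt, ds$patients, cohort = "CP-CML")
#> adjudicated/any/CP-CML: 57/270 (21%)
```

The committee confirmed AOEs in 17% of patients versus 25% flagged by the
broad preferred-term label — the screening/adjudication gap the pipeline
exists to quantify. Each outcome carries its decision trace:

```r
pl$committee$outcomes[[1]]
#> <outcome EV-P001-3-P001-R001: UA_hospitalization [AOE/cardiovascular]>
pl$committee$outcomes[[1]]$criteria_trace
#>                              criterion status
#> 1          negative_cardiac_biomarkers    met
#> 2              no_evidence_of_acute_MI    met
#> 3 ischemic_discomfort_ge_10min_at_rest    met
#> 4      unscheduled_hospitalization_24h    met
#> 5                   objective_ischemia    met

time_to_first_event_summary(dt)[c("n", "median_months")]
#> $n        78
#> $median_months  14.1
for (s in risk_factor_strata(dt, ds$patients)) print(s)
#> risk factors 0: 2/80 (3%)
#> risk factors 1-2: 24/189 (13%)
#> risk factors >=3: 52/180 (29%)
```

Synthetic trials with configurable hazards come from the generator:

```r
ds2 <- generate_trial(generator_config(n_patients = 500, seed = 42))
pl2 <- aoe_pipeline(ds2)
```

A command-line front end (`inst/cli/aoe.R`) exposes the stages as
`simulate | screen | group | adjudicate | analyze` subcommands over
CSV/JSONL study tables.

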