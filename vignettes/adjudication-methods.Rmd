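---
title: "Retrospective adjudication of arterial occlusive events: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Retrospective adjudication of arterial occlusive events: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aoe)
```

## The problem

Safety databases of oncology trials code adverse events (AEs) as MedDRA
preferred terms (PTs). Counting every vascular-sounding PT as an arterial
occlusive event (AOE) overstates risk: many records are symptoms ("chest
pain"), investigations ("troponin increased") or presumptive diagnoses that
an expert committee would not confirm. The remedy used in cardiovascular
outcome trials is *endpoint adjudication*: an independent committee reviews
each candidate event against prespecified, charter-defined criteria and
confirms or rejects it. This package implements that process end to end as
a deterministic, testable pipeline for a ponatinib-treated leukemia
population (four cohorts: chronic-, accelerated- and blast-phase CML and
Ph+ ALL), together with the incidence analytics the adjudicated events feed.

The pipeline stages are:

1. **Screening** (`screen_adverse_events()`): exact matching of normalized
   PTs against a packaged 604-term AOE list plus a heart-failure term set,
   and chair review of all deaths the investigator did not attribute to
   disease progression (`screen_deaths()`).
2. **Grouping** (`group_into_candidate_events()`): records of one patient
   whose onsets fall within 48 hours of each other — directly or through a
   chain — are one candidate clinical event.
3. **Classification** (`adjudicate_candidate_event()` and the per-endpoint
   `classify_*()` functions): a rule engine encodes the charter definitions
   (MI types 1/2/4a/4b/4c/5, heart-failure hospitalization and urgent visit,
   hospitalization for unstable angina, stroke subtypes, SVT/DVT/PE,
   peripheral vascular disease, and cause-of-death categories) and emits a
   criterion-by-criterion trace.
4. **Committee workflow** (`adjudicate_case()`, `run_committee()`): two
   independent reviews, third-cardiologist escalation, specialty panels for
   the stroke/DVT/PE/PVD route, and consensus for fatal events.
5. **Analytics** (`patient_level_rates()`, `exposure_adjusted_incidence()`,
   `risk_factor_strata()`, `dose_modification_summary()`,
   `resolution_summary()`, `time_to_first_event_summary()`,
   `relative_risk_serious_aoe()`).

## Evidence model and the unknown-evidence policy

Retrospective case packages are incomplete, so every evidence field is
tri-state: a known value, a known absence (explicit `FALSE` or an empty
set), or unknown (field omitted). Criteria evaluate in Kleene logic to
`met`, `not_met` or `unknown`. For automatic classification an unknown
criterion counts as `not_met` — the committee cannot confirm what it cannot
see — and when unknowns alone block an otherwise-met endpoint the outcome
carries a `panel_review` flag, mirroring the charter's rule that such
judgment calls require full-committee consensus. Panels in this
implementation resolve deterministically under the same conservative
policy; the policy is a parameter (`unknown_policy`) for sensitivity
analyses.

A few charter clauses are consumed as pre-abstracted booleans rather than
raw measurements, because trial databases store coded findings, not
waveforms or ballots: ECG findings (`new_ST_elevation`, ...), the
angiographic-complication arm of type-4a MI (represented by the
`graft_or_native_occlusion` imaging flag), and the death voting-form items
(`death_witnessed_arrest`, `death_procedure_context`, `death_cv_hemorrhage`,
`death_hf_worsening`, `death_specific_other_cv`, `death_specific_non_cv`)
plus `hf_urgent_visit`, `hf_oral_diuretic_only` and `svt_documented`.

Thresholds are encoded exactly as printed: troponin ratios above 5x and 10x
the 99th-percentile upper reference limit are strict inequalities; 10-minute
rest angina, the 24-hour stroke duration ("24 h or more"), 24-hour stays and
the 50%/70% stenosis cutoffs are non-strict. The test-suite pins each
boundary with epsilon probes.

## Grouping semantics

The charter states only that events more than 48 h apart are independent
and that closer records may represent a single evolving event. For three
records at 0/40/80 h the pairwise rule is ambiguous; this package chains
transitively (single linkage), because the charter's reading treats a run
of related records as one clinical course. Clusters are the connected
components of the pairwise-gap graph, computed by union-find; when either
record lacks a time of day the gap is evaluated at date granularity, with
two calendar days or less counting as within the window. The cluster onset
for analytics is the earliest member onset. The test suite proves
equivalence with a brute-force graph oracle over a thousand random layouts,
including mixed date-only/hour records, where a sorted-chain shortcut is
*not* equivalent (this was caught by the oracle during development and the
implementation switched to true connected components).

Mixed clusters whose terms span both panel routes are adjudicated on the
cardiology route first, then the neuro-vascular route; the first met
endpoint wins. Term-based routing is a heuristic over PT substrings; the
charter does not describe how mixed clusters were routed.

## The committee model

Reviewers are rule engines. A *perturbed* reviewer flips each criterion of
the engine-chosen endpoint's trace independently with probability `p`
(seeded); any flip changes the vote. This gives the exact closed form
`P(vote differs from engine) = 1 - (1-p)^K` for a K-criterion trace, and
two-reviewer disagreement `2a(1-a)` with `a = 1-(1-p)^K`. Note the
disagreement is *not* globally monotone in `p`: past `a = 1/2` both
reviewers flip so often that they increasingly agree on the flipped vote.
Monotonicity of escalation is therefore asserted (and should only be
expected) in the perturbation regime `a < 1/2`. The perturbed reviewer
exists to exercise escalation paths, not to model inter-rater psychology.

Blinding holds by construction: the candidate-event type carries no
ponatinib dose level and no investigator causality assessment. The
AE-level dose action (interrupted/reduced/withdrawn) *is* visible because
the charter's symptom-recording exclusion explicitly conditions on
accompanying medication changes.

## Analytics conventions

* Percentages round half away from zero to integers (forced by a published
  2/80 printed as 3%), property-tested against exact integer arithmetic.
* Months are days / 30.4375; patient-years are days / 365.25.
* Exposure for incidence accrues from first dose to the first qualifying
  event or last contact; later yearly intervals exclude patients with prior
  events. The censoring rule is an assumption (the source does not state
  one); a `censor` switch is exposed.
* Patient-level "serious" is the OR of member-record regulatory
  seriousness; committee classification never overrides the regulatory flag.
* The per-patient worst dose action uses the severity order withdrawn >
  reduced+interrupted > reduced > interrupted > none, with
  interrupted-then-withdrawn as its own row counting toward
  discontinuation, and unknown actions in "not applicable/unknown".
* Non-adjudicated rates are *labels carried on input records* (the trial's
  original, broader PT categorization), never recomputed from the 604-term
  screen: the two lists differ and conflating them would fabricate the
  published comparison.

## Synthetic data: what it emulates and what it does not

`generate_trial()` draws, per patient: a cohort (270/85/62/32 proportions),
six baseline risk factors at the published prevalences (hypertension 0.53,
hypercholesterolemia 0.49, obesity 0.24, diabetes 0.16, non-ischemic
cardiac history 0.43, ischemic history 0.23), an exponential exposure
duration (mean 24 months, capped at 73), and a latent AOE process with
yearly-piecewise-constant hazard `baseline x prod(factor effects) x
decay^floor(t)`. Defaults: baseline 0.035 per patient-year, factor effects
1.2-2.0, decay 0.85 so first-year incidence dominates later years
(qualitative only; no published figure values are encoded as truth). True
events emit one or two in-list records with evidence satisfying their
endpoint; symptom-only noise and out-of-list nuisance records are layered
on top. One RNG substream per patient is derived from the master seed, so
enlarging a cohort never perturbs existing patients. Within-patient event
correlation is uncharacterized in the source; the generator uses a renewal
process with a configurable post-event hazard multiplier (default 1).

The generator does **not** emulate dosing dynamics, efficacy,
informative censoring, or correlated risk factors; a green simulation test
establishes that the pipeline's logic is correct under the stated model,
not that the model reproduces real pharmacovigilance data.

`build_paper_calibrated_fixture()` is different in kind: a *constructive*
449-patient layout whose records are arranged so that running the real
pipeline reproduces the published marginals exactly (cohort sizes, 12,224
records, 455 flagged across 181 patients, 45 fatal reviews, 78/74
adjudicated/serious patients, 111/90 non-adjudicated, risk strata
80/189/180 with 2/24/52 events, 43/35 single/multi with 32/19 resolutions,
the dose-action distribution, the 14.1 (0.1-49.5) months time-to-onset
summary, and 11 fatal AOEs). It is calibration, not fitting: the fixture
validates aggregation logic and makes no claim of patient-level fidelity.
Published per-category breakdowns (cardiovascular/cerebrovascular/
peripheral) are intentionally not constrained. The screening funnel's
455 + 45 = 500 > 490 arithmetic is resolved by letting exactly 10 fatal
records carry in-list terms (so they are already flagged and deduplicate),
the only reading consistent with the published totals; it is an assumption,
recorded as such.

The transcription of the published fatal-event listing ships as
`table12_fixture()`; only its row-level accounting (11 rows, 9 with any
baseline cardiovascular history or risk factors, 2 Ph+ ALL) is asserted.

## Design choices where the design was open

* **TIA**: no TIA endpoint exists; suspected TIAs failing stroke criteria
  return `not_an_event`, consistent with an adjudicated TIA count of zero.
* **Amaurosis fugax** is a PT-level veto on the retinal-artery endpoint.
* **Carotid artery stenosis** without a neurological event is categorized
  cerebrovascular by anatomy, following the published table placement.
* **MI subtype precedence**: confirmed stent thrombosis (4b) wins over 4a;
  restenosis (4c) is evaluated last because its definition requires that no
  other classification fits; procedural contexts win over spontaneous.
* **Exposure-adjusted published values** (13.8/10.6/8.9/8.4 per 100
  patient-years) are not reproduction targets because total patient-years
  is never published; the estimator is instead validated by closed form,
  interval-exclusion checks, and an unbiasedness test against a known
  constant hazard.
* **YAML configs** were replaced by JSON (no YAML parser in the deployment
  environment); the CLI surface is otherwise unchanged.

## Known limitations

The cardiac-failure term list is an editable stand-in (the real SMQ is
proprietary). Free-text narratives are out of scope; evidence arrives
pre-abstracted. The committee model cannot reproduce genuine expert
disagreement rates — no escalation-frequency target exists in the source,
and none is claimed. Stroke disability scoring and survival modeling are
out of scope.
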