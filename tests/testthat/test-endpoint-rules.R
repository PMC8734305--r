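test_that("MI subtypes follow the charter criteria and precedence", {
  t1 <- classify_myocardial_infarction(evidence_package(
    mi_context = "spontaneous", troponin_ratio_to_URL = 2,
    troponin_rise_fall = TRUE, ecg = "new_ST_elevation"))
  expect_equal(t1$endpoint, "MI_type1")

  t4a <- classify_myocardial_infarction(evidence_package(
    mi_context = "post_PCI_24h", baseline_biomarker_normal = TRUE,
    troponin_ratio_to_URL = 6, ecg = "new_ST_depression_or_Twave"))
  expect_equal(t4a$endpoint, "MI_type4a")

  below <- classify_myocardial_infarction(evidence_package(
    mi_context = "post_PCI_24h", baseline_biomarker_normal = TRUE,
    troponin_ratio_to_URL = 4, ecg = "new_ST_depression_or_Twave"))
  expect_null(below$endpoint)

  t5 <- classify_myocardial_infarction(evidence_package(
    mi_context = "post_CABG", baseline_biomarker_normal = TRUE,
    troponin_ratio_to_URL = 12, ecg = "pathological_Q_waves"))
  expect_equal(t5$endpoint, "MI_type5")

  # confirmed stent thrombosis outranks the periprocedural criteria
  t4b <- classify_myocardial_infarction(evidence_package(
    mi_context = "post_PCI_24h", baseline_biomarker_normal = TRUE,
    troponin_ratio_to_URL = 6, troponin_rise_fall = TRUE,
    symptoms = "ischemic_discomfort", ecg = "new_ST_elevation",
    imaging = "stent_thrombus_confirmed"))
  expect_equal(t4b$endpoint, "MI_type4b")
})

test_that("biomarker thresholds are sharp exactly at the printed cutoffs", {
  ev4a <- function(r) evidence_package(
    mi_context = "post_PCI_24h", baseline_biomarker_normal = TRUE,
    troponin_ratio_to_URL = r, ecg = "new_ST_elevation")
  expect_null(classify_myocardial_infarction(ev4a(5))$endpoint)
  expect_equal(classify_myocardial_infarction(ev4a(5 + 1e-9))$endpoint,
               "MI_type4a")
  ev5 <- function(r) evidence_package(
    mi_context = "post_CABG", baseline_biomarker_normal = TRUE,
    troponin_ratio_to_URL = r, ecg = "pathological_Q_waves")
  expect_null(classify_myocardial_infarction(ev5(10))$endpoint)
  expect_equal(classify_myocardial_infarction(ev5(10 + 1e-9))$endpoint,
               "MI_type5")
})

test_that("heart failure events need signs, symptoms and real intensification", {
  base <- list(hf_primary_diagnosis = TRUE, symptoms = "dyspnea",
               hf_exam_findings_count = 2,
               hospitalization = list(admit_day = 0, discharge_day = 3,
                                      unscheduled = TRUE,
                                      within_24h_of_symptoms = TRUE,
                                      primary_diagnosis = "HF"))
  hf <- classify_heart_failure_event(
    do.call(evidence_package, c(base, hf_treatment_intensified = TRUE)))
  expect_equal(hf$endpoint, "HF_hospitalization")
  # no intensification, no event
  none <- classify_heart_failure_event(
    do.call(evidence_package, c(base, hf_treatment_intensified = FALSE)))
  expect_null(none$endpoint)
  # urgent visit with oral diuretics only is insufficient
  urgent <- list(hf_primary_diagnosis = TRUE, symptoms = "dyspnea",
                 hf_exam_findings_count = 2, hf_urgent_visit = TRUE,
                 hf_treatment_intensified = TRUE)
  oral <- classify_heart_failure_event(
    do.call(evidence_package, c(urgent, hf_oral_diuretic_only = TRUE)))
  expect_null(oral$endpoint)
  iv <- classify_heart_failure_event(
    do.call(evidence_package, c(urgent, hf_oral_diuretic_only = FALSE)))
  expect_equal(iv$endpoint, "HF_urgent_visit")
  # one exam finding plus one lab criterion also satisfies the signs rule
  onelab <- classify_heart_failure_event(evidence_package(
    hf_primary_diagnosis = TRUE, symptoms = "orthopnea",
    hf_exam_findings_count = 1, hf_lab_findings_count = 1,
    hf_treatment_intensified = TRUE,
    hospitalization = list(admit_day = 0, discharge_day = 2,
                           unscheduled = TRUE, within_24h_of_symptoms = TRUE,
                           primary_diagnosis = "HF")))
  expect_equal(onelab$endpoint, "HF_hospitalization")
})

test_that("HF attribution follows the cause lists with unknown flagged for panel", {
  expect_true(attribute_heart_failure_to_aoe(
    evidence_package(hf_underlying_cause = "coronary_artery_disease"))$attributed)
  expect_false(attribute_heart_failure_to_aoe(
    evidence_package(hf_underlying_cause = "valve_disorder"))$attributed)
  unk <- attribute_heart_failure_to_aoe(evidence_package())
  expect_false(unk$attributed)
  expect_true(unk$panel_review)
})

test_that("unstable angina requires negative biomarkers and objective ischemia", {
  base <- list(troponin_rise_fall = FALSE, ckmb_above_URL = FALSE,
               symptoms = "ischemic_discomfort_ge_10min_at_rest",
               hospitalization = list(admit_day = 0, discharge_day = 2,
                                      unscheduled = TRUE,
                                      within_24h_of_symptoms = TRUE,
                                      primary_diagnosis = "UA"),
               ecg = "new_ST_depression_or_Twave")
  ua <- classify_unstable_angina_hospitalization(do.call(evidence_package, base))
  expect_equal(ua$endpoint, "UA_hospitalization")
  # a troponin rise/fall above the URL routes to MI logic, not UA
  pos <- base
  pos$troponin_rise_fall <- TRUE
  pos$troponin_ratio_to_URL <- 3
  expect_null(classify_unstable_angina_hospitalization(
    do.call(evidence_package, pos))$endpoint)
  # rest angina under 10 minutes fails
  short <- base
  short$symptoms <- "ischemic_discomfort"
  expect_null(classify_unstable_angina_hospitalization(
    do.call(evidence_package, short))$endpoint)
})

test_that("stroke criteria, the 24-h boundary and subtype mapping", {
  ok <- classify_stroke(evidence_package(
    symptoms = "focal_neuro_deficit", neuro_deficit_duration_hours = 30,
    imaging = "brain_CT_or_MRI_infarct", neuro_confirmation = "specialist",
    non_stroke_cause_present = FALSE))
  expect_equal(ok$endpoint, "stroke_ischemic")

  # short deficit, no intervention, no lesion, survived: not a stroke
  short <- classify_stroke(evidence_package(
    symptoms = "focal_neuro_deficit", neuro_deficit_duration_hours = 2,
    stroke_abort_intervention = FALSE, imaging = character(),
    neuro_confirmation = "specialist", non_stroke_cause_present = FALSE))
  expect_null(short$endpoint)

  # 24 h exactly is in ("24 h or more"); just under is out
  at24 <- classify_stroke(evidence_package(
    symptoms = "focal_neuro_deficit", neuro_deficit_duration_hours = 24,
    stroke_abort_intervention = FALSE, imaging = character(),
    neuro_confirmation = "specialist", non_stroke_cause_present = FALSE))
  expect_equal(at24$endpoint, "stroke_undetermined")
  under24 <- classify_stroke(evidence_package(
    symptoms = "focal_neuro_deficit",
    neuro_deficit_duration_hours = 24 - 1e-9,
    stroke_abort_intervention = FALSE, imaging = character(),
    neuro_confirmation = "specialist", non_stroke_cause_present = FALSE))
  expect_null(under24$endpoint)

  # hemorrhagic transformation of an infarct stays ischemic
  transf <- classify_stroke(evidence_package(
    symptoms = "focal_neuro_deficit", neuro_deficit_duration_hours = 30,
    imaging = c("brain_CT_or_MRI_infarct", "brain_hemorrhage"),
    neuro_confirmation = "brain_imaging", non_stroke_cause_present = FALSE))
  expect_equal(transf$endpoint, "stroke_ischemic")

  # an "infarction" preferred term forces the ischemic subtype
  pt_forced <- classify_stroke(evidence_package(
    symptoms = "focal_neuro_deficit", neuro_deficit_duration_hours = 30,
    imaging = "brain_hemorrhage", neuro_confirmation = "specialist",
    non_stroke_cause_present = FALSE), pts = "Cerebral infarction")
  expect_equal(pt_forced$endpoint, "stroke_ischemic")

  # amaurosis fugax is vetoed from the retinal endpoint
  retinal <- classify_stroke(evidence_package(
    symptoms = "focal_neuro_deficit", neuro_deficit_duration_hours = 30,
    imaging = character(), neuro_confirmation = "specialist",
    non_stroke_cause_present = FALSE), pts = "Retinal artery occlusion")
  expect_equal(retinal$endpoint, "stroke_retinal_artery")
  af <- classify_stroke(evidence_package(
    symptoms = "focal_neuro_deficit", neuro_deficit_duration_hours = 30,
    imaging = character(), neuro_confirmation = "specialist",
    non_stroke_cause_present = FALSE),
    pts = c("Retinal artery occlusion", "Amaurosis fugax"))
  expect_false(identical(af$endpoint, "stroke_retinal_artery"))
})

test_that("venous events and PVD require documentation and are AOEs only when arterial", {
  dvt <- classify_venous_event(evidence_package(
    imaging = "venous_ultrasound_or_venogram_positive",
    vte_location = "lower_limb"))
  expect_equal(dvt$endpoint, "DVT")
  expect_equal(dvt$vte_location, "lower_limb")
  expect_false(derive_endpoint_category("DVT")$is_aoe)

  pe <- classify_venous_event(evidence_package(
    imaging = "pulmonary_CT_or_VQ_positive"))
  expect_equal(pe$endpoint, "PE")
  expect_false(derive_endpoint_category("PE")$is_aoe)

  svt <- classify_venous_event(evidence_package(svt_documented = TRUE))
  expect_equal(svt$endpoint, "SVT")

  art <- classify_peripheral_vascular_disease(evidence_package(
    imaging = "doppler_or_ABI_or_angio_PVD", pvd_vessel_side = "arterial"))
  expect_equal(art$endpoint, "PVD_arterial")
  ven <- classify_peripheral_vascular_disease(evidence_package(
    imaging = "doppler_or_ABI_or_angio_PVD", pvd_vessel_side = "venous"))
  expect_equal(ven$endpoint, "PVD_venous")
  expect_false(derive_endpoint_category("PVD_venous")$is_aoe)
  none <- classify_peripheral_vascular_disease(evidence_package(
    imaging = character()))
  expect_null(none$endpoint)
})

test_that("death causes follow the charter precedence", {
  d <- list(witnessed = FALSE, last_seen_alive_hours_before = 20,
            death_day = 100)
  # death 10 days after an adjudicated MI takes MI precedence over HF signs
  hist <- data.frame(endpoint = "MI_type1", onset_day = 90)
  out <- classify_death_cause(d, evidence_package(death_hf_worsening = TRUE),
                              history = hist)
  expect_equal(out$endpoint, "CV_death_MI")
  # unwitnessed, seen alive 20 h before, no non-CV evidence: sudden death
  out <- classify_death_cause(d, evidence_package(death_specific_non_cv = FALSE))
  expect_equal(out$endpoint, "CV_death_sudden")
  # not seen for days with no cause: undetermined
  d2 <- list(witnessed = FALSE, last_seen_alive_hours_before = 96,
             death_day = 100)
  out <- classify_death_cause(d2, evidence_package(death_specific_non_cv = FALSE))
  expect_equal(out$endpoint, "undetermined_death")
  # periprocedural death from an elective coronary procedure
  out <- classify_death_cause(d, evidence_package(death_procedure_context = TRUE))
  expect_equal(out$endpoint, "CV_death_procedure")
})

test_that("symptom-only clusters are excluded unless anatomy or severity intervene", {
  sympt <- make_candidate(make_package("a", pt = "Non-cardiac chest pain",
                                       grade = 1, dose = "none",
                                       serious = FALSE))
  expect_equal(evaluate_symptom_only_exclusion(sympt), "excluded_not_aoe")
  anat <- make_candidate(make_package(
    "a", pt = "Intermittent claudication", grade = 1, dose = "none",
    serious = FALSE, anatomic = "severe superficial femoral artery stenosis"))
  expect_equal(evaluate_symptom_only_exclusion(anat), "proceed")
  hosp <- make_candidate(make_package(
    "a", pt = "Angina pectoris", grade = 3, dose = "none",
    evidence = evidence_package(hospitalization = list(
      admit_day = 0, discharge_day = 2, unscheduled = TRUE,
      within_24h_of_symptoms = TRUE, primary_diagnosis = "angina"))))
  expect_equal(evaluate_symptom_only_exclusion(hosp), "proceed")
})

test_that("endpoint-to-category mapping matches the published table layout", {
  expect_equal(derive_endpoint_category("MI_type1"),
               list(is_aoe = TRUE, category = "cardiovascular"))
  expect_equal(derive_endpoint_category("stroke_ischemic"),
               list(is_aoe = TRUE, category = "cerebrovascular"))
  expect_equal(derive_endpoint_category("PVD_arterial", "Peripheral artery occlusion"),
               list(is_aoe = TRUE, category = "peripheral_vascular"))
  # carotid disease is categorized by anatomy
  expect_equal(derive_endpoint_category("PVD_arterial", "Carotid artery stenosis")$category,
               "cerebrovascular")
  # hypertension preferred terms never yield an AOE
  expect_false(derive_endpoint_category("MI_type1", "Arterial hypertension")$is_aoe)
  expect_error(derive_endpoint_category("nonsense"), "unmapped")
})

test_that("unknown evidence blocks classification conservatively but flags the panel", {
  # everything needed for type-1 MI except the ECG/imaging support, which is
  # unknown rather than absent
  res <- classify_myocardial_infarction(evidence_package(
    mi_context = "spontaneous", troponin_ratio_to_URL = 3,
    troponin_rise_fall = TRUE))
  expect_null(res$endpoint)
  expect_true(res$panel_review)
  # with support known absent there is nothing for a panel to resolve
  res2 <- classify_myocardial_infarction(evidence_package(
    mi_context = "spontaneous", troponin_ratio_to_URL = 3,
    troponin_rise_fall = TRUE, ecg = character(), imaging = character()))
  expect_null(res2$endpoint)
  expect_false(res2$panel_review)
})

test_that("traces are deterministic and their met criteria replay", {
  ev <- make_candidate(make_package(
    "a", pt = "Acute myocardial infarction",
    evidence = evidence_package(mi_context = "spontaneous",
                                troponin_ratio_to_URL = 3,
                                troponin_rise_fall = TRUE,
                                ecg = "new_ST_elevation")))
  o1 <- adjudicate_candidate_event(ev)
  o2 <- adjudicate_candidate_event(ev)
  expect_identical(o1$criteria_trace, o2$criteria_trace)
  expect_identical(o1$endpoint, o2$endpoint)
  expect_true(isTRUE(replay_trace(o1, ev)))
})
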