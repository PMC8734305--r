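# Charter rule engine: deterministic classification of a candidate event (or
# a death) against the prespecified cardiovascular endpoint definitions.
#
# Every criterion evaluates to met / not_met / unknown on the tri-state
# evidence. For automatic classification an unknown criterion counts as
# not_met (the conservative policy); when unknowns alone block an otherwise
# met endpoint the outcome is flagged `panel_review`, mirroring the charter's
# rule that judgment calls need full committee consensus.
#
# Printed thresholds are encoded exactly as the charter states them:
# troponin > 5x and > 10x the 99th-percentile URL are strict; >= 10 min
# ischemic discomfort, >= 24 h deficit duration and stay, >= 50% / >= 70%
# stenosis are non-strict.

ENDPOINTS <- c(
  "MI_type1", "MI_type2", "MI_type4a", "MI_type4b", "MI_type4c", "MI_type5",
  "HF_hospitalization", "HF_urgent_visit", "UA_hospitalization",
  "stroke_ischemic", "stroke_hemorrhagic", "stroke_retinal_artery",
  "stroke_undetermined", "SVT", "DVT", "PE", "PVD_arterial", "PVD_venous",
  "CV_death_MI", "CV_death_sudden", "CV_death_HF", "CV_death_stroke",
  "CV_death_procedure", "CV_death_hemorrhage", "CV_death_other",
  "non_CV_death", "undetermined_death", "not_an_event"
)

st_enum <- function(x, target) {
  if (is.null(x) || length(x) == 0 || is.na(x)) ST_UNK
  else if (x == target) ST_MET else ST_NOT
}

all_met <- function(statuses, unknown_policy = "not_met") {
  all(st_resolve(statuses, unknown_policy) == ST_MET)
}

trace_df <- function(statuses) {
  data.frame(criterion = names(statuses), status = unname(statuses),
             stringsAsFactors = FALSE)
}

# ---- myocardial infarction ---------------------------------------------------

ISCHEMIC_ECG <- c("new_ST_elevation", "new_ST_depression_or_Twave", "new_LBBB")
IMAGING_LOSS <- c("new_nonviable_myocardium", "new_wall_motion_abnormality")
ISCHEMIC_SYMPTOMS <- c("ischemic_discomfort", "ischemic_discomfort_ge_10min_at_rest")

# "rise and/or fall with at least one value above the URL"
st_tn_above_url <- function(ev) {
  st_and(st_bool(ev$troponin_rise_fall),
         st_gt(ev$troponin_ratio_to_URL, 1, strict = TRUE))
}

st_biomarker_positive <- function(ev) {
  st_or(st_tn_above_url(ev), st_bool(ev$ckmb_above_URL))
}

mi_criteria_sets <- function(ev) {
  tn_above <- st_tn_above_url(ev)
  biomarker <- st_biomarker_positive(ev)
  ischemia_support <- st_or(
    st_has(ev$imaging, IMAGING_LOSS),
    st_has(ev$ecg, ISCHEMIC_ECG),
    st_has(ev$ecg, "pathological_Q_waves"))
  list(
    # stent thrombosis wins over 4a when angiographically confirmed
    MI_type4b = c(
      stent_thrombosis_confirmed = st_has(ev$imaging, "stent_thrombus_confirmed"),
      ischemic_symptoms = st_has(ev$symptoms, ISCHEMIC_SYMPTOMS),
      troponin_rise_fall_above_URL = tn_above),
    MI_type4a = c(
      post_PCI_within_24h = st_enum(ev$mi_context, "post_PCI_24h"),
      biomarker_periprocedural = st_or(
        st_and(st_bool(ev$baseline_biomarker_normal),
               st_gt(ev$troponin_ratio_to_URL, 5, strict = TRUE)),
        st_and(st_not(st_bool(ev$baseline_biomarker_normal)),
               st_bool(ev$troponin_rise_fall),
               st_bool(ev$biomarker_decreasing_prior))),
      supporting_finding = st_or(
        st_has(ev$symptoms, ISCHEMIC_SYMPTOMS),
        st_has(ev$ecg, ISCHEMIC_ECG),
        st_has(ev$imaging, "graft_or_native_occlusion"),
        st_has(ev$imaging, IMAGING_LOSS))),
    MI_type5 = c(
      post_CABG = st_enum(ev$mi_context, "post_CABG"),
      troponin_gt_10x_URL_normal_baseline = st_and(
        st_gt(ev$troponin_ratio_to_URL, 10, strict = TRUE),
        st_bool(ev$baseline_biomarker_normal)),
      supporting_finding = st_or(
        st_has(ev$ecg, c("pathological_Q_waves", "new_LBBB")),
        st_has(ev$imaging, "graft_or_native_occlusion"),
        st_has(ev$imaging, IMAGING_LOSS))),
    MI_type1 = c(
      spontaneous_ischemia = st_enum(ev$mi_context, "spontaneous"),
      biomarker_positive = biomarker,
      supporting_finding = ischemia_support),
    MI_type2 = c(
      supply_demand_context = st_enum(ev$mi_context, "supply_demand"),
      biomarker_positive = biomarker,
      supporting_finding = ischemia_support),
    # evaluated last: requires that no other MI classification fits
    MI_type4c = c(
      stent_restenosis_ge_50pct = st_has(ev$imaging, "stent_restenosis_ge_50pct"),
      ischemic_symptoms = st_has(ev$symptoms, ISCHEMIC_SYMPTOMS),
      biomarker_above_URL = st_gt(ev$troponin_ratio_to_URL, 1, strict = TRUE))
  )
}

#' Classify a myocardial infarction from merged evidence
#'
#' Applies the universal-definition subtype criteria in charter precedence
#' order (confirmed stent thrombosis 4b, then periprocedural 4a/5, then
#' spontaneous 1 / supply-demand 2, with restenosis 4c last since it requires
#' that no other classification fits). At most one subtype is returned.
#'
#' @param ev an `aoe_evidence` package (merged over the cluster).
#' @param unknown_policy how unknown criteria resolve during classification.
#' @return list with `endpoint` (an MI subtype or NULL), `trace`
#'   (criterion/status data.frame of the decisive subtype) and
#'   `panel_review` (TRUE when unknowns alone blocked a subtype).
#' @export
classify_myocardial_infarction <- function(ev, unknown_policy = "not_met") {
  sets <- mi_criteria_sets(ev)
  panel <- FALSE
  for (type in names(sets)) {
    crit <- sets[[type]]
    if (type == "MI_type4c") {
      others <- vapply(sets[names(sets) != "MI_type4c"],
                       all_met, logical(1), unknown_policy = unknown_policy)
      crit <- c(crit, no_other_MI_classification =
                  if (any(others)) ST_NOT else ST_MET)
    }
    if (all_met(crit, unknown_policy))
      return(list(endpoint = type, trace = trace_df(crit), panel_review = FALSE))
    if (!all_met(crit, "not_met") && all_met(crit, "met")) panel <- TRUE
  }
  list(endpoint = NULL, trace = trace_df(sets$MI_type1), panel_review = panel)
}

# ---- heart failure -----------------------------------------------------------

HF_SYMPTOMS <- c("dyspnea", "orthopnea", "PND", "decreased_exercise_tolerance",
                 "fatigue")

st_hosp_stay_24h <- function(ev) {
  h <- ev$hospitalization
  if (is.null(h)) return(ST_NOT)  # no hospitalization documented
  if (is.null(h$admit_day) || is.null(h$discharge_day) ||
      is.na(h$admit_day) || is.na(h$discharge_day)) return(ST_UNK)
  if (h$discharge_day - h$admit_day >= 1) ST_MET else ST_NOT  # calendar change
}

hf_criteria_sets <- function(ev) {
  signs <- st_or(
    st_gt(ev$hf_exam_findings_count, 2, strict = FALSE),
    st_and(st_gt(ev$hf_exam_findings_count, 1, strict = FALSE),
           st_gt(ev$hf_lab_findings_count, 1, strict = FALSE)))
  common <- c(
    primary_HF_diagnosis = st_bool(ev$hf_primary_diagnosis),
    new_or_worsening_HF_symptom = st_has(ev$symptoms, HF_SYMPTOMS),
    objective_HF_signs = signs)
  list(
    HF_hospitalization = c(common,
      hospital_stay_ge_24h = st_hosp_stay_24h(ev),
      treatment_intensified = st_bool(ev$hf_treatment_intensified)),
    HF_urgent_visit = c(common,
      urgent_unscheduled_visit = st_bool(ev$hf_urgent_visit),
      not_meeting_hospitalization = st_not(st_hosp_stay_24h(ev)),
      treatment_beyond_oral_diuretic = st_and(
        st_bool(ev$hf_treatment_intensified),
        st_not(st_bool(ev$hf_oral_diuretic_only))))
  )
}

#' Classify a heart-failure event
#'
#' Hospitalization for heart failure requires a primary HF diagnosis, a stay
#' of at least 24 h (or a calendar-date change), at least one HF symptom,
#' objective signs (two exam findings, or one exam plus one laboratory
#' finding) and initiation/intensification of HF treatment. An urgent
#' unscheduled visit meeting the same sign/symptom/treatment criteria — with
#' oral diuretic augmentation alone being insufficient — is an urgent HF
#' visit.
#'
#' @inheritParams classify_myocardial_infarction
#' @export
classify_heart_failure_event <- function(ev, unknown_policy = "not_met") {
  sets <- hf_criteria_sets(ev)
  panel <- FALSE
  for (type in names(sets)) {
    crit <- sets[[type]]
    if (all_met(crit, unknown_policy))
      return(list(endpoint = type, trace = trace_df(crit), panel_review = FALSE))
    if (!all_met(crit, "not_met") && all_met(crit, "met")) panel <- TRUE
  }
  list(endpoint = NULL, trace = trace_df(sets$HF_hospitalization),
       panel_review = panel)
}

#' Attribute an established heart-failure event to an AOE
#'
#' TRUE iff the underlying cause is coronary artery disease, hypertension,
#' cardiomyopathy or myocardial infarction; FALSE for valve disorders,
#' congenital disease or arrhythmias. An unknown cause defaults to FALSE
#' with a panel flag.
#'
#' @param ev an `aoe_evidence` package.
#' @return list with `attributed` (logical) and `panel_review`.
#' @export
attribute_heart_failure_to_aoe <- function(ev) {
  cause <- ev$hf_underlying_cause
  if (is.null(cause) || is.na(cause) || cause == "unknown")
    return(list(attributed = FALSE, panel_review = TRUE))
  list(attributed = cause %in% c("coronary_artery_disease", "hypertension",
                                 "cardiomyopathy", "myocardial_infarction"),
       panel_review = FALSE)
}

# ---- unstable angina ---------------------------------------------------------

st_hosp_unscheduled_24h <- function(ev) {
  h <- ev$hospitalization
  if (is.null(h)) return(ST_NOT)
  st_and(st_bool(h$unscheduled), st_bool(h$within_24h_of_symptoms),
         st_hosp_stay_24h(ev))
}

ua_criteria <- function(ev, no_mi_status = ST_MET) {
  c(negative_cardiac_biomarkers = st_not(st_biomarker_positive(ev)),
    no_evidence_of_acute_MI = no_mi_status,
    ischemic_discomfort_ge_10min_at_rest =
      st_has(ev$symptoms, "ischemic_discomfort_ge_10min_at_rest"),
    unscheduled_hospitalization_24h = st_hosp_unscheduled_24h(ev),
    objective_ischemia = st_or(
      st_has(ev$ecg, c("new_ST_depression_or_Twave", "transient_ST_elevation")),
      st_has(ev$imaging, "angiographic_culprit_lesion_ge_70pct"),
      st_has(ev$procedure, "revascularization_for_culprit")))
}

#' Classify hospitalization for unstable angina
#'
#' Requires negative cardiac biomarkers with no MI classification, rest
#' ischemic discomfort of 10 minutes or more, an unscheduled hospitalization
#' within 24 h of symptoms lasting at least 24 h, and at least one objective
#' ischemia finding (new/worsening ST-T changes, transient ST elevation,
#' a culprit lesion of at least 70% stenosis, or revascularization of the
#' presumed culprit lesion).
#'
#' @inheritParams classify_myocardial_infarction
#' @export
classify_unstable_angina_hospitalization <- function(ev, unknown_policy = "not_met") {
  mi <- classify_myocardial_infarction(ev, unknown_policy)
  no_mi <- if (is.null(mi$endpoint)) ST_MET else ST_NOT
  crit <- ua_criteria(ev, no_mi)
  met <- all_met(crit, unknown_policy)
  list(endpoint = if (met) "UA_hospitalization" else NULL,
       trace = trace_df(crit),
       panel_review = !met && !all_met(crit, "not_met") && all_met(crit, "met"))
}

# ---- stroke ------------------------------------------------------------------

stroke_general_criteria <- function(ev, fatal = FALSE) {
  c(acute_neuro_deficit = st_has(ev$symptoms,
                                 c("focal_neuro_deficit", "global_neuro_deficit")),
    duration_or_confirmation = st_or(
      st_gt(ev$neuro_deficit_duration_hours, 24, strict = FALSE),
      st_bool(ev$stroke_abort_intervention),
      st_has(ev$imaging, c("brain_CT_or_MRI_infarct", "brain_hemorrhage")),
      if (fatal) ST_MET else ST_NOT),
    no_non_stroke_cause = st_not(st_bool(ev$non_stroke_cause_present)),
    diagnosis_confirmed = st_has(ev$neuro_confirmation, NEURO_CONFIRMATION))
}

stroke_subtype <- function(ev, pts = character()) {
  n <- normalize_pt(pts)
  retinal_pt <- any(grepl("retinal arter", n)) && !any(grepl("amaurosis fugax", n))
  infarct_pt <- any(grepl("infarct", n))
  img <- ev$imaging
  if (retinal_pt) return("stroke_retinal_artery")
  if (!is.null(img) && "brain_CT_or_MRI_infarct" %in% img) return("stroke_ischemic")
  if (infarct_pt) return("stroke_ischemic")  # "infarction" PT forces ischemic
  if (!is.null(img) && "brain_hemorrhage" %in% img) return("stroke_hemorrhagic")
  "stroke_undetermined"
}

#' Classify a stroke and its subtype
#'
#' Stroke requires an acute focal/global neurological deficit, a duration of
#' 24 h or more (or < 24 h with an aborting intervention, imaging-documented
#' lesion, or death before 24 h), no plausible non-stroke cause, and at least
#' one confirmation source. Subtype comes from imaging: infarct is ischemic
#' (hemorrhagic transformation of an infarct stays ischemic), isolated
#' hemorrhage is hemorrhagic, retinal-artery terms map to the retinal
#' endpoint (amaurosis fugax is vetoed), otherwise undetermined. A preferred
#' term containing "infarction" forces the ischemic subtype.
#'
#' @inheritParams classify_myocardial_infarction
#' @param pts member preferred terms of the candidate event.
#' @param fatal TRUE when the deficit ended in death before 24 h.
#' @export
classify_stroke <- function(ev, pts = character(), fatal = FALSE,
                            unknown_policy = "not_met") {
  crit <- stroke_general_criteria(ev, fatal)
  met <- all_met(crit, unknown_policy)
  if (met) {
    sub <- stroke_subtype(ev, pts)
    return(list(endpoint = sub, trace = trace_df(crit), panel_review = FALSE))
  }
  list(endpoint = NULL, trace = trace_df(crit),
       panel_review = !all_met(crit, "not_met") && all_met(crit, "met"))
}

# ---- venous events and PVD ---------------------------------------------------

venous_criteria_sets <- function(ev) {
  list(
    PE = c(pulmonary_imaging_positive = st_has(ev$imaging, "pulmonary_CT_or_VQ_positive")),
    DVT = c(deep_vein_clot_documented = st_has(ev$imaging, "venous_ultrasound_or_venogram_positive")),
    SVT = c(superficial_clot_documented = st_bool(ev$svt_documented))
  )
}

#' Classify venous thromboembolic events
#'
#' DVT requires a deep-vein clot documented by a listed modality
#' (ultrasound / CUS / IPG / venography / CT / MRI / autopsy, collapsed to
#' one imaging flag); PE requires documentation by CT, angiogram, V/Q scan
#' or autopsy; SVT is documented clinically or by duplex. Venous events are
#' never AOEs.
#'
#' @inheritParams classify_myocardial_infarction
#' @export
classify_venous_event <- function(ev, unknown_policy = "not_met") {
  sets <- venous_criteria_sets(ev)
  panel <- FALSE
  for (type in names(sets)) {
    crit <- sets[[type]]
    if (all_met(crit, unknown_policy)) {
      out <- list(endpoint = type, trace = trace_df(crit), panel_review = FALSE)
      out$vte_location <- ev$vte_location
      return(out)
    }
    if (!all_met(crit, "not_met") && all_met(crit, "met")) panel <- TRUE
  }
  list(endpoint = NULL, trace = trace_df(sets$DVT), panel_review = panel)
}

#' Classify peripheral vascular disease
#'
#' PVD requires documentation by a listed modality (Doppler ultrasound,
#' ankle-brachial index, angiography, MR/CT angiography, collapsed to one
#' imaging flag) and a vessel-side call: arterial PVD is an AOE in the
#' peripheral-vascular category, venous PVD is not an AOE.
#'
#' @inheritParams classify_myocardial_infarction
#' @export
classify_peripheral_vascular_disease <- function(ev, unknown_policy = "not_met") {
  crit <- c(
    documented_by_listed_modality = st_has(ev$imaging, "doppler_or_ABI_or_angio_PVD"),
    vessel_side_recorded = if (is.null(ev$pvd_vessel_side) ||
                               is.na(ev$pvd_vessel_side)) ST_UNK else ST_MET)
  if (all_met(crit, unknown_policy)) {
    side <- ev$pvd_vessel_side
    ep <- if (identical(side, "venous")) "PVD_venous" else "PVD_arterial"
    return(list(endpoint = ep, trace = trace_df(crit), panel_review = FALSE))
  }
  list(endpoint = NULL, trace = trace_df(crit),
       panel_review = !all_met(crit, "not_met") && all_met(crit, "met"))
}

# ---- symptom-only exclusion --------------------------------------------------

# symptom / descriptor preferred terms that record complaints, not diagnoses
AOE_SYMPTOM_TERMS <- normalize_pt(c(
  "Angina pectoris", "Anginal equivalent", "Chest pain", "Chest discomfort",
  "Non-cardiac chest pain", "Cardiac discomfort", "Intermittent claudication",
  "Claudication of jaw muscles", "Ischaemic limb pain", "Peripheral coldness",
  "Dependent rubor", "Poor peripheral circulation"
))

#' Symptom-recording exclusion
#'
#' Events recorded purely as symptoms (e.g. non-cardiac chest pain,
#' claudication) with low severity, no accompanying dose change and no
#' hospitalization were adjudicated to not be AOEs — unless an anatomic
#' diagnosis was provided.
#'
#' @param ev an `aoe_candidate` event.
#' @return `"excluded_not_aoe"` or `"proceed"`.
#' @export
evaluate_symptom_only_exclusion <- function(ev) {
  stopifnot(inherits(ev, "aoe_candidate"))
  all_symptom <- all(normalize_pt(ev$member_pts) %in% AOE_SYMPTOM_TERMS)
  low_grade <- all(is.na(ev$member_grades) | ev$member_grades <= 2)
  no_dose_change <- all(is.na(ev$member_dose_actions) |
                          ev$member_dose_actions == "none")
  # an unknown dose action on a pure symptom record is treated as no change
  no_hosp <- is.null(ev$merged_evidence$hospitalization)
  no_anatomic <- length(ev$anatomic_diagnoses) == 0
  if (all_symptom && low_grade && no_dose_change && no_hosp && no_anatomic)
    "excluded_not_aoe" else "proceed"
}

# ---- death cause -------------------------------------------------------------

death_criteria_sets <- function(d, ev, mi_met, stroke_met) {
  list(
    CV_death_MI = c(death_within_30d_of_MI = mi_met),
    CV_death_stroke = c(death_within_30d_of_stroke = stroke_met),
    CV_death_procedure = c(procedure_complication = st_bool(ev$death_procedure_context)),
    CV_death_hemorrhage = c(cv_hemorrhage = st_or(
      st_bool(ev$death_cv_hemorrhage),
      st_and(st_has(ev$imaging, "brain_hemorrhage"), st_not(stroke_met)))),
    CV_death_HF = c(worsening_HF_signs = st_or(st_bool(ev$death_hf_worsening),
                                               st_bool(ev$hf_primary_diagnosis))),
    CV_death_sudden = c(sudden_death_rule = st_or(
      st_and(st_bool(d$witnessed), st_bool(ev$death_witnessed_arrest)),
      st_and(st_not(st_bool(d$witnessed)),
             st_gt(24 - (d$last_seen_alive_hours_before %||% NA_real_), 0,
                   strict = FALSE),
             st_not(st_bool(ev$death_specific_non_cv))))),
    CV_death_other = c(specific_other_CV_cause = st_bool(ev$death_specific_other_cv)),
    non_CV_death = c(specific_non_CV_cause = st_bool(ev$death_specific_non_cv))
  )
}

#' Adjudicate the cause of a death
#'
#' Applies the charter's precedence: death within 30 days of an adjudicated
#' MI (or from a procedure treating one), then stroke death, procedural
#' death, CV hemorrhage, heart-failure death, sudden cardiac death (witnessed
#' arrest, or unwitnessed but seen alive and stable within 24 h with no
#' evidence of a non-CV cause), other specific CV causes (pulmonary embolism,
#' peripheral arterial or venous disease), specific non-CV causes, and
#' finally undetermined (including a patient not seen alive within 24 h of
#' being found dead with no cause established).
#'
#' @param d one row of the deaths table (as a list): `witnessed`,
#'   `last_seen_alive_hours_before`, `death_day`.
#' @param ev merged `aoe_evidence` for the death narrative.
#' @param history optional data.frame of prior adjudicated outcomes for the
#'   patient with columns `endpoint` and `onset_day`; an MI or stroke within
#'   30 days before `death_day` triggers the corresponding death category.
#' @param unknown_policy unknown-criterion resolution.
#' @return list with `endpoint`, `trace`, `panel_review`.
#' @export
classify_death_cause <- function(d, ev, history = NULL,
                                 unknown_policy = "not_met") {
  mi_recent <- ST_NOT
  stroke_recent <- ST_NOT
  if (!is.null(history) && nrow(history)) {
    gap <- d$death_day - history$onset_day
    recent <- gap >= 0 & gap <= 30
    if (any(recent & grepl("^MI_", history$endpoint))) mi_recent <- ST_MET
    if (any(recent & grepl("^stroke_", history$endpoint))) stroke_recent <- ST_MET
  }
  mi_ev <- classify_myocardial_infarction(ev, unknown_policy)
  mi_met <- st_or(mi_recent, if (is.null(mi_ev$endpoint)) ST_NOT else ST_MET)
  stroke_ev <- classify_stroke(ev, fatal = TRUE, unknown_policy = unknown_policy)
  stroke_met <- st_or(stroke_recent,
                      if (is.null(stroke_ev$endpoint)) ST_NOT else ST_MET)
  sets <- death_criteria_sets(d, ev, mi_met, stroke_met)
  panel <- FALSE
  for (type in names(sets)) {
    crit <- sets[[type]]
    if (all_met(crit, unknown_policy))
      return(list(endpoint = type, trace = trace_df(crit),
                  panel_review = FALSE))
    if (!all_met(crit, "not_met") && all_met(crit, "met")) panel <- TRUE
  }
  list(endpoint = "undetermined_death",
       trace = trace_df(c(no_category_attributable = ST_MET)),
       panel_review = panel)
}

# ---- category map ------------------------------------------------------------

HYPERTENSION_PTS <- normalize_pt(c("Hypertension", "Arterial hypertension",
                                   "Hypertensive crisis"))

CEREBRO_ANATOMY_PATTERNS <- c("carotid", "cerebr", "precerebral", "basilar",
                              "vertebral arter", "intracranial")
VENOUS_DEATH_PATTERNS <- c("pulmonary embolism", "vein thrombosis",
                           "venous thrombosis", "embolism venous")

#' Map an endpoint to its AOE flag and category
#'
#' Coronary endpoints (MI subtypes, unstable angina, coronary deaths, sudden
#' death) are cardiovascular; stroke subtypes, stroke/hemorrhage deaths and
#' carotid/cerebral arterial disease are cerebrovascular; arterial PVD and
#' peripheral arterial deaths are peripheral vascular. Venous events (SVT,
#' DVT, PE, venous PVD), non-CV and undetermined deaths, and non-events are
#' not AOEs. Arterial-hypertension preferred terms never produce an AOE
#' category. Heart-failure endpoints are AOEs only when attributed.
#'
#' @param endpoint one of the endpoint enum values.
#' @param pts member preferred terms (used for anatomy-based category calls).
#' @param hf_attributed attribution flag for heart-failure endpoints.
#' @return list with `is_aoe` and `category` (or NA).
#' @export
derive_endpoint_category <- function(endpoint, pts = character(),
                                     hf_attributed = NA) {
  if (!endpoint %in% ENDPOINTS) stop("unmapped endpoint: ", endpoint)
  n <- normalize_pt(pts)
  if (length(n) && all(n %in% HYPERTENSION_PTS))
    return(list(is_aoe = FALSE, category = NA_character_))
  cerebro_anatomy <- any(vapply(CEREBRO_ANATOMY_PATTERNS,
                                function(p) any(grepl(p, n)), logical(1)))
  if (endpoint %in% c("MI_type1", "MI_type2", "MI_type4a", "MI_type4b",
                      "MI_type4c", "MI_type5", "UA_hospitalization",
                      "CV_death_MI", "CV_death_sudden", "CV_death_procedure"))
    return(list(is_aoe = TRUE, category = "cardiovascular"))
  if (endpoint %in% c("stroke_ischemic", "stroke_hemorrhagic",
                      "stroke_retinal_artery", "stroke_undetermined",
                      "CV_death_stroke", "CV_death_hemorrhage"))
    return(list(is_aoe = TRUE, category = "cerebrovascular"))
  if (endpoint %in% c("HF_hospitalization", "HF_urgent_visit", "CV_death_HF")) {
    if (isTRUE(hf_attributed))
      return(list(is_aoe = TRUE, category = "cardiovascular"))
    return(list(is_aoe = FALSE, category = NA_character_))
  }
  if (endpoint == "PVD_arterial")
    return(list(is_aoe = TRUE,
                category = if (cerebro_anatomy) "cerebrovascular"
                           else "peripheral_vascular"))
  if (endpoint == "CV_death_other") {
    venous <- any(vapply(VENOUS_DEATH_PATTERNS,
                         function(p) any(grepl(p, n)), logical(1)))
    if (venous) return(list(is_aoe = FALSE, category = NA_character_))
    return(list(is_aoe = TRUE,
                category = if (cerebro_anatomy) "cerebrovascular"
                           else "peripheral_vascular"))
  }
  # SVT / DVT / PE / PVD_venous / non_CV_death / undetermined_death /
  # not_an_event
  list(is_aoe = FALSE, category = NA_character_)
}

# ---- candidate-event driver --------------------------------------------------

LEFT_CLASSIFIERS <- c("mi", "hf", "ua")
RIGHT_CLASSIFIERS <- c("stroke", "venous", "pvd")

#' Adjudicate one candidate event with the deterministic rule engine
#'
#' Runs the symptom-only exclusion, then the endpoint classifiers of the
#' event's panel route (cardiology route: MI, heart failure, unstable
#' angina; neurology/vascular route: stroke, venous events, PVD; a mixed
#' cluster runs both, cardiology first). Fatal-review events are classified
#' by the death-cause rules instead.
#'
#' @param ev an `aoe_candidate` event.
#' @param death_record list with the patient's death row when `ev` is under
#'   fatal review.
#' @param history prior outcomes data.frame for death precedence.
#' @param unknown_policy unknown-criterion resolution.
#' @return an `aoe_outcome`: endpoint, is_aoe, category, serious,
#'   revascularization_associated, criteria_trace, panel_review.
#' @export
adjudicate_candidate_event <- function(ev, death_record = NULL, history = NULL,
                                       unknown_policy = "not_met") {
  stopifnot(inherits(ev, "aoe_candidate"))
  me <- ev$merged_evidence
  outcome <- function(endpoint, trace, panel, hf_attr = NA) {
    cat_map <- derive_endpoint_category(endpoint, ev$member_pts, hf_attr)
    structure(list(
      event_id = ev$event_id, patient_id = ev$patient_id,
      endpoint = endpoint, is_aoe = cat_map$is_aoe,
      category = cat_map$category, serious = ev$serious,
      fatal = ev$fatal, onset_day = ev$onset_day,
      revascularization_associated =
        if (is.null(me$procedure)) NA
        else any(c("PCI", "CABG", "PVI") %in% me$procedure),
      criteria_trace = trace, panel_review = panel,
      member_record_ids = ev$member_record_ids,
      member_resolved = ev$member_resolved,
      dose_actions = ev$member_dose_actions
    ), class = "aoe_outcome")
  }

  if (ev$fatal || ev$fatal_review) {
    if (is.null(death_record))
      stop("fatal candidate ", ev$event_id, " needs its death record")
    res <- classify_death_cause(death_record, me, history, unknown_policy)
    return(outcome(res$endpoint, res$trace, res$panel_review,
                   hf_attr = attribute_heart_failure_to_aoe(me)$attributed))
  }

  if (evaluate_symptom_only_exclusion(ev) == "excluded_not_aoe")
    return(outcome("not_an_event",
                   trace_df(c(symptom_only_exclusion = ST_MET)), FALSE))

  routes <- switch(ev$route,
    AOE_HF_route = LEFT_CLASSIFIERS,
    stroke_DVT_PE_PVD_route = RIGHT_CLASSIFIERS,
    both_routes = c(LEFT_CLASSIFIERS, RIGHT_CLASSIFIERS))
  panel <- FALSE
  for (cl in routes) {
    res <- switch(cl,
      mi = classify_myocardial_infarction(me, unknown_policy),
      hf = classify_heart_failure_event(me, unknown_policy),
      ua = classify_unstable_angina_hospitalization(me, unknown_policy),
      stroke = classify_stroke(me, ev$member_pts, fatal = ev$fatal,
                               unknown_policy = unknown_policy),
      venous = classify_venous_event(me, unknown_policy),
      pvd = classify_peripheral_vascular_disease(me, unknown_policy))
    panel <- panel || res$panel_review
    if (!is.null(res$endpoint)) {
      hf_attr <- NA
      if (res$endpoint %in% c("HF_hospitalization", "HF_urgent_visit")) {
        at <- attribute_heart_failure_to_aoe(me)
        hf_attr <- at$attributed
        panel <- panel || at$panel_review
      }
      return(outcome(res$endpoint, res$trace, panel, hf_attr))
    }
  }
  outcome("not_an_event", trace_df(c(no_endpoint_criteria_met = ST_MET)), panel)
}

#' @export
print.aoe_outcome <- function(x, ...) {
  cat("<outcome ", x$event_id, ": ", x$endpoint,
      if (isTRUE(x$is_aoe)) paste0(" [AOE/", x$category, "]") else "",
      if (x$panel_review) " (panel review)", ">\n", sep = "")
  invisible(x)
}

#' Re-evaluate the `met` criteria of an outcome against stored evidence
#'
#' Soundness check used by the test-suite: every criterion recorded as `met`
#' in the trace must re-evaluate to `met` on the evidence that produced it.
#' @param out an `aoe_outcome`.
#' @param ev the candidate event it came from.
#' @param death_record,history as in [adjudicate_candidate_event()].
#' @return TRUE or a character vector of criteria that failed to replay.
#' @export
replay_trace <- function(out, ev, death_record = NULL, history = NULL) {
  re <- adjudicate_candidate_event(ev, death_record, history)
  a <- out$criteria_trace; b <- re$criteria_trace
  m <- merge(a[a$status == "met", ], b, by = "criterion",
             suffixes = c("_old", "_new"))
  bad <- m$criterion[m$status_new != "met"]
  if (length(bad)) bad else TRUE
}
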