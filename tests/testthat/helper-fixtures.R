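# Shared fixtures and independent oracles. Everything is built in code.

quiet <- function(expr) suppressMessages(suppressWarnings(expr))

# ---- minimal in-memory case packages / candidate events ---------------------

# one case package as assemble_case_packages() would emit it
make_package <- function(record_id, patient_id = "P1", pt = "Myocardial infarction",
                         onset_day = 10, onset_hour = NA, grade = 3,
                         dose = "none", serious = TRUE, fatal = FALSE,
                         resolved = FALSE, anatomic = NA_character_,
                         evidence = evidence_package(), fatal_review = FALSE) {
  list(record_id = record_id, patient_id = patient_id,
       ae = list(record_id = record_id, patient_id = patient_id,
                 preferred_term = pt, onset_day = onset_day,
                 onset_hour = onset_hour, resolution_day = NA,
                 resolved = resolved, severity_grade = grade,
                 serious = serious, dose_action = dose,
                 anatomic_diagnosis = anatomic, fatal = fatal),
       evidence = evidence, fatal_review = fatal_review)
}

# a single-cluster candidate event from one or more package specs
make_candidate <- function(..., window_hours = 48) {
  pkgs <- list(...)
  names(pkgs) <- vapply(pkgs, function(p) p$record_id, character(1))
  evs <- quiet(group_into_candidate_events(pkgs, window_hours))
  stopifnot(length(evs) == 1)
  evs[[1]]
}

# a tiny valid study dataset (built fresh each call)
make_toy_study <- function() {
  patients <- data.table::data.table(
    patient_id = c("P1", "P2"),
    cohort = c("CP-CML", "AP-CML"),
    age_years = c(55L, 61L), sex = c("male", "female"),
    risk_factors = c("arterial_hypertension;diabetes_mellitus", ""),
    first_dose_day = c(1L, 1L), last_contact_day = c(400L, 300L))
  aes <- data.table::data.table(
    record_id = paste0("R", 1:5),
    patient_id = c("P1", "P1", "P1", "P2", "P2"),
    preferred_term = c("Myocardial infarction", "Troponin increased",
                       "Nausea", "Cerebral infarction", "Headache"),
    onset_day = c(100L, 101L, 50L, 120L, 10L),
    onset_hour = NA_integer_,
    resolution_day = c(130L, 130L, 55L, NA, 12L),
    resolved = c(TRUE, TRUE, TRUE, FALSE, TRUE),
    severity_grade = c(3L, 3L, 1L, 3L, 1L),
    serious = c(TRUE, TRUE, FALSE, TRUE, FALSE),
    dose_action = c("interrupted", "interrupted", "none", "none", "none"),
    anatomic_diagnosis = NA_character_,
    fatal = FALSE, nonadjudicated_aoe = c(TRUE, TRUE, FALSE, TRUE, FALSE))
  deaths <- data.table::data.table(
    patient_id = character(), record_id = character(), death_day = integer(),
    last_seen_alive_hours_before = numeric(), witnessed = logical(),
    progression_attributed = logical())
  evidence <- list(
    R1 = evidence_package(mi_context = "spontaneous",
                          troponin_ratio_to_URL = 3, troponin_rise_fall = TRUE,
                          ecg = "new_ST_elevation",
                          symptoms = "ischemic_discomfort"),
    R4 = evidence_package(symptoms = "focal_neuro_deficit",
                          neuro_deficit_duration_hours = 48,
                          imaging = "brain_CT_or_MRI_infarct",
                          neuro_confirmation = "specialist",
                          non_stroke_cause_present = FALSE))
  aoe:::new_study_dataset(patients, aes, deaths, evidence)
}

# write a toy study to disk, return the path list load_study_tables() wants
write_toy_tables <- function(ds, dir) {
  quiet(write_study_tables(ds, dir))
  list(patients = file.path(dir, "patients.csv"),
       adverse_events = file.path(dir, "adverse_events.csv"),
       deaths = file.path(dir, "deaths.csv"),
       evidence = file.path(dir, "evidence.jsonl"))
}

# ---- grouping oracle: brute-force connected components ----------------------

# onsets: data.frame(day, hour) with NA hour for date-only records
oracle_gap_hours <- function(d1, h1, d2, h2) {
  if (is.na(h1) || is.na(h2)) abs(d1 - d2) * 24
  else abs(((d1 - 1) * 24 + h1) - ((d2 - 1) * 24 + h2))
}

oracle_components <- function(onsets, window_hours = 48) {
  n <- nrow(onsets)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j && !is.na(onsets$day[i]) && !is.na(onsets$day[j]))
      adj[i, j] <- oracle_gap_hours(onsets$day[i], onsets$hour[i],
                                    onsets$day[j], onsets$hour[j]) <= window_hours
  }
  comp <- rep(NA_integer_, n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (!is.na(comp[s])) next
    cur <- cur + 1L
    queue <- s
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (!is.na(comp[v])) next
      comp[v] <- cur
      queue <- c(queue, which(adj[v, ] & is.na(comp)))
    }
  }
  # records without onset are singletons by construction
  comp
}

partition_sets <- function(ids, comp) {
  unname(lapply(split(ids, comp), function(x) sort(x)))
}

canon_partition <- function(sets) {
  s <- lapply(unname(sets), function(x) unname(sort(x)))
  s[order(vapply(s, function(x) x[1], character(1)))]
}

# ---- independent endpoint oracles (transcribed from the charter text) -------
# These take *discrete* field states and answer whether the endpoint's
# printed definition is satisfied, with an unknown state treated as failing
# the clause it appears in (the committee cannot confirm it automatically).

tri <- function(x) identical(x, TRUE)          # TRUE only when known TRUE
known_num <- function(x) !is.null(x) && !is.na(x)

oracle_mi <- function(f) {
  # f: list(context, rise_fall, ratio, ckmb, baseline_normal, decreasing,
  #         ecg (chr vec or NULL), imaging (chr vec or NULL), symptoms)
  has <- function(set, items) !is.null(set) && any(items %in% set)
  tn_above <- tri(f$rise_fall) && known_num(f$ratio) && f$ratio > 1
  biomarker <- tn_above || tri(f$ckmb)
  isch_ecg <- has(f$ecg, c("new_ST_elevation", "new_ST_depression_or_Twave",
                           "new_LBBB"))
  q_wave <- has(f$ecg, "pathological_Q_waves")
  img_loss <- has(f$imaging, c("new_nonviable_myocardium",
                               "new_wall_motion_abnormality"))
  support <- img_loss || isch_ecg || q_wave
  symp <- has(f$symptoms, c("ischemic_discomfort",
                            "ischemic_discomfort_ge_10min_at_rest"))
  ctx <- function(v) identical(f$context, v)

  t4b <- has(f$imaging, "stent_thrombus_confirmed") && symp && tn_above
  t4a <- ctx("post_PCI_24h") &&
    ((tri(f$baseline_normal) && known_num(f$ratio) && f$ratio > 5) ||
     (identical(f$baseline_normal, FALSE) && tri(f$rise_fall) &&
        tri(f$decreasing))) &&
    (symp || isch_ecg || has(f$imaging, "graft_or_native_occlusion") || img_loss)
  t5 <- ctx("post_CABG") && known_num(f$ratio) && f$ratio > 10 &&
    tri(f$baseline_normal) &&
    (q_wave || has(f$ecg, "new_LBBB") ||
       has(f$imaging, "graft_or_native_occlusion") || img_loss)
  t1 <- ctx("spontaneous") && biomarker && support
  t2 <- ctx("supply_demand") && biomarker && support
  t4c_core <- has(f$imaging, "stent_restenosis_ge_50pct") && symp &&
    known_num(f$ratio) && f$ratio > 1
  if (t4b) return("MI_type4b")
  if (t4a) return("MI_type4a")
  if (t5) return("MI_type5")
  if (t1) return("MI_type1")
  if (t2) return("MI_type2")
  if (t4c_core) return("MI_type4c")
  NULL
}

oracle_hf <- function(f) {
  # f: list(primary, urgent, oral_only, symptoms, exam, lab, treatment, hosp)
  #   hosp: NULL (none) | list(stay_days) | "unknown_stay"
  has_symp <- !is.null(f$symptoms) && any(c(
    "dyspnea", "orthopnea", "PND", "decreased_exercise_tolerance",
    "fatigue") %in% f$symptoms)
  signs <- (known_num(f$exam) && f$exam >= 2) ||
    (known_num(f$exam) && f$exam >= 1 && known_num(f$lab) && f$lab >= 1)
  stay24 <- is.list(f$hosp) && known_num(f$hosp$stay_days) && f$hosp$stay_days >= 1
  common <- tri(f$primary) && has_symp && signs
  if (common && stay24 && tri(f$treatment)) return("HF_hospitalization")
  no_stay24 <- is.null(f$hosp) ||
    (is.list(f$hosp) && known_num(f$hosp$stay_days) && f$hosp$stay_days < 1)
  if (common && tri(f$urgent) && no_stay24 && tri(f$treatment) &&
      identical(f$oral_only, FALSE)) return("HF_urgent_visit")
  NULL
}

oracle_ua <- function(f) {
  # f: rise_fall, ratio, ckmb, rest_angina, hosp (NULL | list(unscheduled,
  #     within24, stay_days) ), ecg, culprit, revasc
  # "negative cardiac biomarkers" must be positively established: the
  # troponin arm is known negative (no rise/fall, or peak at/below the URL)
  # and CK-MB is known not elevated
  troponin_negative <- identical(f$rise_fall, FALSE) ||
    (known_num(f$ratio) && f$ratio <= 1)
  negative <- troponin_negative && identical(f$ckmb, FALSE)
  hosp_ok <- is.list(f$hosp) && tri(f$hosp$unscheduled) &&
    tri(f$hosp$within24) && known_num(f$hosp$stay_days) && f$hosp$stay_days >= 1
  objective <- (!is.null(f$ecg) && any(c("new_ST_depression_or_Twave",
                                         "transient_ST_elevation") %in% f$ecg)) ||
    (!is.null(f$culprit) && "angiographic_culprit_lesion_ge_70pct" %in% f$culprit) ||
    (!is.null(f$revasc) && "revascularization_for_culprit" %in% f$revasc)
  if (negative && tri(f$rest_angina) && hosp_ok && objective)
    "UA_hospitalization" else NULL
}

oracle_stroke <- function(f) {
  # f: deficit, duration, abort, imaging, non_stroke_cause, confirm, fatal, pts
  deficit <- !is.null(f$deficit) && any(c("focal_neuro_deficit",
                                          "global_neuro_deficit") %in% f$deficit)
  lesion <- !is.null(f$imaging) && any(c("brain_CT_or_MRI_infarct",
                                         "brain_hemorrhage") %in% f$imaging)
  dur_ok <- (known_num(f$duration) && f$duration >= 24) || tri(f$abort) ||
    lesion || isTRUE(f$fatal)
  no_cause <- identical(f$non_stroke_cause, FALSE)
  confirmed <- !is.null(f$confirm) && length(f$confirm) > 0
  if (!(deficit && dur_ok && no_cause && confirmed)) return(NULL)
  n <- tolower(f$pts %||% character())
  if (any(grepl("retinal arter", n)) && !any(grepl("amaurosis fugax", n)))
    return("stroke_retinal_artery")
  if (!is.null(f$imaging) && "brain_CT_or_MRI_infarct" %in% f$imaging)
    return("stroke_ischemic")
  if (any(grepl("infarct", n))) return("stroke_ischemic")
  if (!is.null(f$imaging) && "brain_hemorrhage" %in% f$imaging)
    return("stroke_hemorrhagic")
  "stroke_undetermined"
}

oracle_death <- function(f) {
  # f: recent (none|mi|stroke), mi_now, stroke_now, procedure, hemorrhage,
  #    brain_hem_img, hf, witnessed, arrest, last_seen, other_cv, non_cv
  stroke_now <- isTRUE(f$stroke_now)
  if (identical(f$recent, "mi") || isTRUE(f$mi_now)) return("CV_death_MI")
  if (identical(f$recent, "stroke") || stroke_now) return("CV_death_stroke")
  if (tri(f$procedure)) return("CV_death_procedure")
  if (tri(f$hemorrhage) || (isTRUE(f$brain_hem_img) && !stroke_now))
    return("CV_death_hemorrhage")
  if (tri(f$hf)) return("CV_death_HF")
  sudden <- (tri(f$witnessed) && tri(f$arrest)) ||
    (identical(f$witnessed, FALSE) && known_num(f$last_seen) &&
       f$last_seen <= 24 && identical(f$non_cv, FALSE))
  if (sudden) return("CV_death_sudden")
  if (tri(f$other_cv)) return("CV_death_other")
  if (tri(f$non_cv)) return("non_CV_death")
  "undetermined_death"
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# discretized tri-state grids used by the enumeration tests
TRI_BOOL <- list(TRUE, FALSE, NULL)
pick <- function(choices, idx) choices[[idx]]

# build an evidence package from a possibly-NULL named list of fields
ev_from <- function(fields) {
  fields <- fields[!vapply(fields, is.null, logical(1))]
  do.call(evidence_package, fields)
}
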