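# Domain types and study-table IO.
#
# A study dataset holds four linked tables, loosely modeled on the CDISC SDTM
# domains a trial safety database exports:
#   patients        (DM-like)  one row per participant
#   adverse_events  (AE-like)  one row per reported AE record
#   deaths          (DS-like)  one row per death
#   evidence        (JSONL)    one clinical-evidence package per AE record
# Study time is measured in 1-based integer study days from first dose; the
# optional onset_hour (0-23) refines onsets to hour granularity where the
# source database recorded a time of day.

COHORTS <- c("CP-CML", "AP-CML", "BP-CML", "Ph+ALL")

RISK_FACTORS <- c(
  "arterial_hypertension", "hypercholesterolemia", "obesity",
  "diabetes_mellitus", "non_ischemic_cardiac_history", "ischemic_history"
)

DOSE_ACTIONS <- c(
  "none", "interrupted", "reduced", "reduced_and_interrupted",
  "withdrawn", "interrupted_then_withdrawn"
)

ECG_FINDINGS <- c(
  "new_ST_elevation", "new_ST_depression_or_Twave", "new_LBBB",
  "pathological_Q_waves", "transient_ST_elevation"
)

IMAGING_FINDINGS <- c(
  "new_nonviable_myocardium", "new_wall_motion_abnormality",
  "brain_CT_or_MRI_infarct", "brain_hemorrhage",
  "angiographic_culprit_lesion_ge_70pct", "stent_thrombus_confirmed",
  "stent_restenosis_ge_50pct", "graft_or_native_occlusion",
  "pulmonary_CT_or_VQ_positive", "doppler_or_ABI_or_angio_PVD",
  "venous_ultrasound_or_venogram_positive"
)

SYMPTOM_FINDINGS <- c(
  "ischemic_discomfort", "ischemic_discomfort_ge_10min_at_rest", "dyspnea",
  "orthopnea", "PND", "decreased_exercise_tolerance", "fatigue",
  "focal_neuro_deficit", "global_neuro_deficit"
)

NEURO_CONFIRMATION <- c("specialist", "brain_imaging", "lumbar_puncture")

PROCEDURES <- c("PCI", "CABG", "PVI", "revascularization_for_culprit",
                "thrombolysis")

MI_CONTEXTS <- c("spontaneous", "supply_demand", "post_PCI_24h",
                 "stent_thrombosis", "stent_restenosis", "post_CABG")

HF_CAUSES <- c("coronary_artery_disease", "hypertension", "cardiomyopathy",
               "myocardial_infarction", "valve_disorder", "congenital",
               "arrhythmia", "unknown")

VTE_LOCATIONS <- c("lower_limb", "upper_limb", "retinal_vein",
                   "abdominal_viscera", "other")

# field -> type used by the constructor and the JSONL reader/writer.
# "ballot" fields (death_*, hf_urgent_visit, hf_oral_diuretic_only,
# svt_documented) abstract checkbox items on the charter voting form.
EVIDENCE_FIELDS <- list(
  troponin_ratio_to_URL = "num",
  troponin_rise_fall = "bool",
  ckmb_above_URL = "bool",
  baseline_biomarker_normal = "bool",
  biomarker_decreasing_prior = "bool",
  ecg = "set",
  imaging = "set",
  symptoms = "set",
  neuro_deficit_duration_hours = "num",
  stroke_abort_intervention = "bool",
  neuro_confirmation = "set",
  non_stroke_cause_present = "bool",
  hf_exam_findings_count = "num",
  hf_lab_findings_count = "num",
  hf_primary_diagnosis = "bool",
  hf_treatment_intensified = "bool",
  hf_oral_diuretic_only = "bool",
  hf_urgent_visit = "bool",
  hf_underlying_cause = "enum",
  hospitalization = "list",
  procedure = "set",
  procedure_timing_hours = "num",
  mi_context = "enum",
  pvd_vessel_side = "enum",
  vte_location = "enum",
  svt_documented = "bool",
  death_witnessed_arrest = "bool",
  death_procedure_context = "bool",
  death_cv_hemorrhage = "bool",
  death_hf_worsening = "bool",
  death_specific_other_cv = "bool",
  death_specific_non_cv = "bool"
)

EVIDENCE_SET_DOMAIN <- list(
  ecg = ECG_FINDINGS, imaging = IMAGING_FINDINGS, symptoms = SYMPTOM_FINDINGS,
  neuro_confirmation = NEURO_CONFIRMATION, procedure = PROCEDURES
)

#' Construct a clinical-evidence package
#'
#' Every field is tri-state: supply a value for known evidence, an explicit
#' `FALSE` / empty vector for evidence known to be absent, or omit the field
#' entirely for unknown. Set-valued fields (`ecg`, `imaging`, `symptoms`,
#' `neuro_confirmation`, `procedure`) take character vectors drawn from the
#' controlled vocabularies in this package.
#'
#' @param ... named evidence fields; see `EVIDENCE_FIELDS` for the schema.
#' @return an object of class `aoe_evidence` (a named list).
#' @export
#' @examples
#' ev <- evidence_package(mi_context = "spontaneous",
#'                        troponin_ratio_to_URL = 3, troponin_rise_fall = TRUE,
#'                        ecg = "new_ST_elevation")
evidence_package <- function(...) {
  ev <- list(...)
  if (length(ev) && (is.null(names(ev)) || any(names(ev) == "")))
    stop("evidence_package(): all fields must be named")
  bad <- setdiff(names(ev), names(EVIDENCE_FIELDS))
  if (length(bad)) stop("unknown evidence field(s): ", paste(bad, collapse = ", "))
  for (f in names(ev)) {
    ty <- EVIDENCE_FIELDS[[f]]
    v <- ev[[f]]
    if (ty == "set") {
      v <- as.character(v)
      dom <- EVIDENCE_SET_DOMAIN[[f]]
      if (!is.null(dom) && length(setdiff(v, dom)))
        stop("field ", f, ": values outside vocabulary: ",
             paste(setdiff(v, dom), collapse = ", "))
      ev[[f]] <- v
    } else if (ty == "num") {
      if (!is.na(v) && v < 0) stop("field ", f, " must be >= 0")
      ev[[f]] <- as.numeric(v)
    } else if (ty == "bool") {
      ev[[f]] <- as.logical(v)
    }
  }
  if (!is.null(ev$mi_context) && !is.na(ev$mi_context) &&
      !ev$mi_context %in% MI_CONTEXTS)
    stop("invalid mi_context: ", ev$mi_context)
  if (!is.null(ev$hf_underlying_cause) &&
      !ev$hf_underlying_cause %in% HF_CAUSES)
    stop("invalid hf_underlying_cause: ", ev$hf_underlying_cause)
  structure(ev, class = "aoe_evidence")
}

# accessor honouring the tri-state convention (missing field -> NULL/unknown)
ev_get <- function(ev, field) ev[[field]]

#' @export
print.aoe_evidence <- function(x, ...) {
  cat("<evidence package:", length(x), "known field(s)>\n")
  for (f in names(x)) {
    v <- x[[f]]
    cat("  ", f, ": ",
        if (is.list(v)) paste(names(v), unlist(v), sep = "=", collapse = ", ")
        else paste(v, collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

PATIENT_COLS <- c("patient_id", "cohort", "age_years", "sex", "risk_factors",
                  "first_dose_day", "last_contact_day")
AE_COLS <- c("record_id", "patient_id", "preferred_term", "onset_day",
             "onset_hour", "resolution_day", "resolved", "severity_grade",
             "serious", "dose_action", "anatomic_diagnosis", "fatal",
             "nonadjudicated_aoe")
DEATH_COLS <- c("patient_id", "record_id", "death_day",
                "last_seen_alive_hours_before", "witnessed",
                "progression_attributed")

new_study_dataset <- function(patients, adverse_events, deaths, evidence,
                              provenance = list()) {
  structure(list(patients = patients, adverse_events = adverse_events,
                 deaths = deaths, evidence = evidence,
                 provenance = provenance),
            class = "aoe_study")
}

#' @export
print.aoe_study <- function(x, ...) {
  cat("<aoe study dataset>\n")
  cat("  patients:      ", nrow(x$patients), "\n")
  cat("  AE records:    ", nrow(x$adverse_events), "\n")
  cat("  deaths:        ", nrow(x$deaths), "\n")
  cat("  evidence keys: ", length(x$evidence), "\n")
  invisible(x)
}

#' Load the study tables into a cross-referenced dataset
#'
#' Reads the delimited DM-like, AE-like and DS-like tables plus the JSONL
#' evidence file. Any malformed row, missing required column or dangling
#' `patient_id` is a hard failure naming the offending column or ids.
#'
#' @param paths named list with elements `patients`, `adverse_events`,
#'   `deaths` (CSV/TSV, header row) and optionally `evidence` (JSON lines,
#'   one object per AE record keyed by `record_id`).
#' @param config optional list of run metadata stored in `provenance`.
#' @return an `aoe_study` dataset.
#' @export
load_study_tables <- function(paths, config = list()) {
  stopifnot(is.list(paths), all(c("patients", "adverse_events") %in% names(paths)))
  read_tbl <- function(path, required, label) {
    if (!file.exists(path)) stop(label, " table not found: ", path)
    dt <- data.table::fread(path, na.strings = c("NA", ""), sep = "auto")
    miss <- setdiff(required, names(dt))
    if (length(miss))
      stop(label, ": missing required column(s): ", paste(miss, collapse = ", "))
    dt
  }
  coerce_cols <- function(dt, types) {
    for (col in names(types)) {
      if (!col %in% names(dt)) next
      fn <- switch(types[[col]], chr = as.character, int = as.integer,
                   num = as.numeric, lgl = as.logical)
      data.table::set(dt, j = col, value = fn(dt[[col]]))
    }
    dt
  }
  patients <- coerce_cols(
    read_tbl(paths$patients, PATIENT_COLS, "patients"),
    c(patient_id = "chr", cohort = "chr", age_years = "int", sex = "chr",
      risk_factors = "chr", first_dose_day = "int", last_contact_day = "int"))
  patients$risk_factors[is.na(patients$risk_factors)] <- ""
  aes <- coerce_cols(
    read_tbl(paths$adverse_events, AE_COLS, "adverse_events"),
    c(record_id = "chr", patient_id = "chr", preferred_term = "chr",
      onset_day = "int", onset_hour = "int", resolution_day = "int",
      resolved = "lgl", severity_grade = "int", serious = "lgl",
      dose_action = "chr", anatomic_diagnosis = "chr", fatal = "lgl",
      nonadjudicated_aoe = "lgl"))
  deaths <- if (!is.null(paths$deaths))
    coerce_cols(read_tbl(paths$deaths, DEATH_COLS, "deaths"),
                c(patient_id = "chr", record_id = "chr", death_day = "int",
                  last_seen_alive_hours_before = "num", witnessed = "lgl",
                  progression_attributed = "lgl"))
            else data.table::data.table(patient_id = character(),
                                        record_id = character(),
                                        death_day = integer(),
                                        last_seen_alive_hours_before = numeric(),
                                        witnessed = logical(),
                                        progression_attributed = logical())
  for (col in c("onset_day", "resolution_day", "severity_grade")) {
    v <- aes[[col]]
    if (!is.numeric(v)) {
      conv <- suppressWarnings(as.numeric(v))
      bad <- which(!is.na(v) & is.na(conv))
      if (length(bad))
        stop("adverse_events: unparseable ", col, " at row(s) ",
             paste(utils::head(bad, 10), collapse = ", "))
      data.table::set(aes, j = col, value = conv)
    }
  }
  dangling <- setdiff(aes$patient_id, patients$patient_id)
  if (length(dangling))
    stop("adverse_events reference unknown patient id(s): ",
         paste(sort(dangling), collapse = ", "))
  dangling_d <- setdiff(deaths$patient_id, patients$patient_id)
  if (length(dangling_d))
    stop("deaths reference unknown patient id(s): ",
         paste(sort(dangling_d), collapse = ", "))
  evidence <- if (!is.null(paths$evidence)) read_evidence_jsonl(paths$evidence)
              else list()
  message(sprintf("loaded %d patients, %d AE records, %d deaths, %d evidence packages",
                  nrow(patients), nrow(aes), nrow(deaths), length(evidence)))
  new_study_dataset(patients, aes, deaths, evidence,
                    provenance = c(config, list(paths = paths)))
}

read_evidence_jsonl <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  out <- list()
  for (i in seq_along(lines)) {
    obj <- jsonlite::fromJSON(lines[[i]], simplifyVector = TRUE,
                              simplifyDataFrame = FALSE)
    rid <- obj$record_id
    if (is.null(rid)) stop("evidence line ", i, " lacks record_id")
    obj$record_id <- NULL
    for (f in names(obj)) {
      if (identical(EVIDENCE_FIELDS[[f]], "set")) obj[[f]] <- as.character(obj[[f]])
    }
    out[[rid]] <- do.call(evidence_package, obj)
  }
  out
}

write_evidence_jsonl <- function(evidence, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (rid in names(evidence)) {
    ev <- evidence[[rid]]
    obj <- c(list(record_id = rid), unclass(ev))
    writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, null = "null",
                                digits = NA), con)
  }
  invisible(path)
}

#' Write a study dataset back to its table files
#'
#' Inverse of [load_study_tables()]: a round-trip reproduces every typed
#' field. Files are written as CSV (RFC-4180 quoting) plus a JSONL evidence
#' file.
#'
#' @param ds an `aoe_study` dataset.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_study_tables <- function(ds, dir) {
  stopifnot(inherits(ds, "aoe_study"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  data.table::fwrite(ds$patients, file.path(dir, "patients.csv"))
  data.table::fwrite(ds$adverse_events, file.path(dir, "adverse_events.csv"))
  data.table::fwrite(ds$deaths, file.path(dir, "deaths.csv"))
  write_evidence_jsonl(ds$evidence, file.path(dir, "evidence.jsonl"))
  invisible(dir)
}

#' Validate a study dataset against the domain invariants
#'
#' Never mutates its input; every invariant breach becomes one report row.
#' An empty report means the dataset is valid.
#'
#' @param ds an `aoe_study` dataset.
#' @return a data.frame with columns `table`, `id`, `problem`.
#' @export
validate_study <- function(ds) {
  stopifnot(inherits(ds, "aoe_study"))
  prob <- list()
  add <- function(table, id, problem)
    prob[[length(prob) + 1]] <<- data.frame(table = table, id = id,
                                            problem = problem)
  p <- ds$patients
  bad <- p$patient_id[!p$cohort %in% COHORTS]
  for (id in bad) add("patients", id, "invalid cohort")
  bad <- p$patient_id[p$first_dose_day > p$last_contact_day]
  for (id in bad) add("patients", id, "first_dose_day > last_contact_day")
  bad <- p$patient_id[!is.na(p$age_years) & p$age_years < 18]
  for (id in bad) add("patients", id, "age_years < 18")
  for (i in seq_len(nrow(p))) {
    rf <- parse_risk_factors(p$risk_factors[i])
    if (length(setdiff(rf, RISK_FACTORS)))
      add("patients", p$patient_id[i], "unknown risk factor")
  }
  a <- ds$adverse_events
  if (anyDuplicated(a$record_id))
    for (id in unique(a$record_id[duplicated(a$record_id)]))
      add("adverse_events", id, "duplicate record_id")
  bad <- a$record_id[!is.na(a$resolution_day) & a$resolution_day < a$onset_day]
  for (id in bad) add("adverse_events", id, "resolution_day < onset_day")
  bad <- a$record_id[a$fatal & !a$serious]
  for (id in bad) add("adverse_events", id, "fatal but not serious")
  bad <- a$record_id[!is.na(a$severity_grade) &
                       (a$severity_grade < 1 | a$severity_grade > 5)]
  for (id in bad) add("adverse_events", id, "severity_grade outside 1-5")
  bad <- a$record_id[!is.na(a$dose_action) & !a$dose_action %in% DOSE_ACTIONS]
  for (id in bad) add("adverse_events", id, "invalid dose_action")
  d <- ds$deaths
  if (nrow(d)) {
    lc <- p$last_contact_day[match(d$patient_id, p$patient_id)]
    bad <- d$patient_id[d$death_day > lc + 1]
    for (id in bad) add("deaths", id, "death_day > last_contact_day + 1")
  }
  if (length(prob)) do.call(rbind, prob)
  else data.frame(table = character(), id = character(), problem = character())
}

# risk_factors travel as a ";"-separated string in the CSV
parse_risk_factors <- function(x) {
  if (is.na(x) || !nzchar(x)) character() else strsplit(x, ";", fixed = TRUE)[[1]]
}

format_risk_factors <- function(rf) paste(rf, collapse = ";")

risk_factor_count <- function(x) {
  vapply(x, function(s) length(parse_risk_factors(s)), integer(1))
}
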