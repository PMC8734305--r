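# Seeded synthetic trials with the statistical structure the analysis
# assumes: per-patient baseline risk factors, a latent AOE process with
# multiplicative factor effects and yearly hazard decay, qualifying evidence
# emitted for true events, symptom-only noise, and out-of-list nuisance AEs.
#
# One pseudo-random substream per patient is derived from the master seed,
# so adding patients never perturbs existing ones.

#' Generator configuration
#'
#' Defaults mirror the reference trial's stated world: four cohorts in the
#' 270/85/62/32 proportions, Table-4-style risk-factor prevalences
#' (hypertension 0.53, hypercholesterolemia 0.49, obesity 0.24, diabetes
#' 0.16, non-ischemic cardiac history 0.43, ischemic history 0.23), a
#' baseline AOE hazard with multiplicative factor effects, and a yearly
#' hazard decay < 1 so first-year incidence dominates later years.
#'
#' @param n_patients number of patients.
#' @param cohort_fractions simplex over the four cohorts.
#' @param risk_factor_prevalences named probabilities for the six factors.
#' @param aoe_hazard list with `baseline` (events per patient-year for a
#'   factor-free patient), `factor_effects` (named multipliers) and `decay`
#'   (multiplier per elapsed year).
#' @param post_event_multiplier hazard multiplier after a first event
#'   (renewal process; within-patient correlation is not characterized in
#'   the source data, so this is a configurable assumption).
#' @param symptom_noise_rate symptom-only in-list AEs per patient-year.
#' @param nuisance_rate out-of-list AEs per patient-year.
#' @param evidence_completeness probability each evidence field is known.
#' @param death_rate probability a patient dies at end of follow-up.
#' @param mean_exposure_months mean of the exponential exposure duration.
#' @param seed master seed.
#' @return a validated `aoe_generator_config` list.
#' @export
generator_config <- function(n_patients = 449,
                             cohort_fractions = c(`CP-CML` = 270, `AP-CML` = 85,
                                                  `BP-CML` = 62, `Ph+ALL` = 32) / 449,
                             risk_factor_prevalences = c(
                               arterial_hypertension = 0.53,
                               hypercholesterolemia = 0.49,
                               obesity = 0.24,
                               diabetes_mellitus = 0.16,
                               non_ischemic_cardiac_history = 0.43,
                               ischemic_history = 0.23),
                             aoe_hazard = list(
                               baseline = 0.035,
                               factor_effects = c(
                                 arterial_hypertension = 1.6,
                                 hypercholesterolemia = 1.5,
                                 obesity = 1.2,
                                 diabetes_mellitus = 1.6,
                                 non_ischemic_cardiac_history = 1.3,
                                 ischemic_history = 2.0),
                               decay = 0.85),
                             post_event_multiplier = 1.0,
                             symptom_noise_rate = 0.25,
                             nuisance_rate = 6,
                             evidence_completeness = 1.0,
                             death_rate = 0.05,
                             mean_exposure_months = 24,
                             seed = 1L) {
  cfg <- list(n_patients = as.integer(n_patients),
              cohort_fractions = cohort_fractions,
              risk_factor_prevalences = risk_factor_prevalences,
              aoe_hazard = aoe_hazard,
              post_event_multiplier = post_event_multiplier,
              symptom_noise_rate = symptom_noise_rate,
              nuisance_rate = nuisance_rate,
              evidence_completeness = evidence_completeness,
              death_rate = death_rate,
              mean_exposure_months = mean_exposure_months,
              seed = as.integer(seed))
  if (cfg$n_patients < 1) stop("n_patients must be >= 1")
  if (abs(sum(cfg$cohort_fractions) - 1) > 1e-8)
    stop("cohort_fractions must sum to 1")
  if (any(cfg$risk_factor_prevalences < 0 | cfg$risk_factor_prevalences > 1))
    stop("prevalences must be in [0, 1]")
  if (cfg$aoe_hazard$baseline < 0 || cfg$aoe_hazard$decay < 0 ||
      cfg$symptom_noise_rate < 0 || cfg$nuisance_rate < 0)
    stop("rates must be >= 0")
  if (cfg$evidence_completeness < 0 || cfg$evidence_completeness > 1)
    stop("evidence_completeness must be in [0, 1]")
  structure(cfg, class = "aoe_generator_config")
}

NUISANCE_PTS <- c("Nausea", "Headache", "Diarrhoea", "Rash", "Pyrexia",
                  "Vomiting", "Arthralgia", "Abdominal pain",
                  "Thrombocytopenia", "Anaemia")

SYMPTOM_NOISE_PTS <- c("Angina pectoris", "Chest pain", "Non-cardiac chest pain",
                       "Chest discomfort", "Intermittent claudication",
                       "Peripheral coldness")

# endpoint -> (lead PT, companion PT, qualifying evidence)
endpoint_blueprints <- function() {
  list(
    MI_type1 = list(
      pts = c("Acute myocardial infarction", "Troponin increased"),
      evidence = function() evidence_package(
        mi_context = "spontaneous", troponin_ratio_to_URL = 3,
        troponin_rise_fall = TRUE, ecg = "new_ST_elevation",
        symptoms = "ischemic_discomfort",
        hospitalization = list(admit_day = NA, discharge_day = NA,
                               unscheduled = TRUE,
                               within_24h_of_symptoms = TRUE,
                               primary_diagnosis = "acute MI"))),
    MI_type4a = list(
      pts = c("Post procedural myocardial infarction", "Troponin increased"),
      evidence = function() evidence_package(
        mi_context = "post_PCI_24h", baseline_biomarker_normal = TRUE,
        troponin_ratio_to_URL = 6, troponin_rise_fall = TRUE,
        ecg = "new_ST_depression_or_Twave", procedure = "PCI",
        procedure_timing_hours = 6)),
    UA_hospitalization = list(
      pts = c("Angina unstable", "Electrocardiogram ST segment depression"),
      evidence = function() evidence_package(
        troponin_ratio_to_URL = 0.5, troponin_rise_fall = FALSE,
        ckmb_above_URL = FALSE,
        symptoms = "ischemic_discomfort_ge_10min_at_rest",
        ecg = "new_ST_depression_or_Twave",
        hospitalization = list(admit_day = 0, discharge_day = 2,
                               unscheduled = TRUE,
                               within_24h_of_symptoms = TRUE,
                               primary_diagnosis = "unstable angina"))),
    HF_hospitalization = list(
      pts = c("Cardiac failure congestive", "Cardiac failure"),
      evidence = function() evidence_package(
        troponin_ratio_to_URL = 0.4, troponin_rise_fall = FALSE,
        ckmb_above_URL = FALSE,
        hf_primary_diagnosis = TRUE, symptoms = "dyspnea",
        hf_exam_findings_count = 2, hf_lab_findings_count = 1,
        hf_treatment_intensified = TRUE, hf_oral_diuretic_only = FALSE,
        hf_underlying_cause = "coronary_artery_disease",
        hospitalization = list(admit_day = 0, discharge_day = 3,
                               unscheduled = TRUE,
                               within_24h_of_symptoms = TRUE,
                               primary_diagnosis = "congestive heart failure"))),
    stroke_ischemic = list(
      pts = c("Cerebral infarction", "Hemiparesis"),
      evidence = function() evidence_package(
        symptoms = "focal_neuro_deficit", neuro_deficit_duration_hours = 36,
        imaging = "brain_CT_or_MRI_infarct", neuro_confirmation = "specialist",
        non_stroke_cause_present = FALSE)),
    PVD_arterial = list(
      pts = c("Peripheral arterial occlusive disease", "Intermittent claudication"),
      evidence = function() evidence_package(
        imaging = "doppler_or_ABI_or_angio_PVD", pvd_vessel_side = "arterial"))
  )
}

# drop evidence fields at random to emulate incomplete retrospective data
thin_evidence <- function(ev, completeness) {
  if (completeness >= 1 || !length(ev)) return(ev)
  keep <- stats::runif(length(ev)) < completeness
  do.call(evidence_package, unclass(ev)[keep])
}

#' Generate a synthetic trial
#'
#' Fully reproducible from the seed. True AOEs arise from a per-patient
#' yearly-piecewise-constant hazard `baseline * prod(factor effects) *
#' decay^floor(t)`; each true event emits one or two in-list AE records with
#' evidence satisfying its endpoint definition; symptom-only noise records
#' carry in-list symptom terms with no qualifying evidence; out-of-list
#' nuisance records pad the AE table. Both true-event and symptom-noise
#' records carry the broad non-adjudicated label, reproducing the direction
#' of the screened-versus-adjudicated rate gap.
#'
#' @param cfg an `aoe_generator_config`.
#' @return an `aoe_study` dataset.
#' @export
generate_trial <- function(cfg = generator_config()) {
  stopifnot(inherits(cfg, "aoe_generator_config"))
  bp <- endpoint_blueprints()
  pat_rows <- vector("list", cfg$n_patients)
  ae_rows <- list()
  death_rows <- list()
  evidence <- list()
  eff <- cfg$aoe_hazard$factor_effects
  for (i in seq_len(cfg$n_patients)) {
    # per-patient substream; double arithmetic avoids 32-bit overflow
    set.seed(as.integer((as.numeric(cfg$seed) * 1000003 + i) %% 2147483647))
    pid <- sprintf("S%05d", i)
    cohort <- sample(names(cfg$cohort_fractions), 1,
                     prob = cfg$cohort_fractions)
    rf <- names(cfg$risk_factor_prevalences)[
      stats::runif(length(cfg$risk_factor_prevalences)) <
        cfg$risk_factor_prevalences]
    exp_months <- pmin(stats::rexp(1, 1 / cfg$mean_exposure_months) + 0.2, 73)
    exp_days <- max(3L, round(exp_months * DAYS_PER_MONTH))
    h0 <- cfg$aoe_hazard$baseline * prod(eff[intersect(rf, names(eff))])
    # event times under yearly piecewise-constant hazard with renewal
    times <- numeric()
    t <- 0
    mult <- 1
    horizon <- exp_days / DAYS_PER_YEAR
    repeat {
      y <- floor(t)
      h <- h0 * cfg$aoe_hazard$decay^y * mult
      if (h <= 0) break
      gap <- stats::rexp(1, h)
      if (t + gap > min(y + 1, horizon)) {
        t <- y + 1
        if (t >= horizon) break
      } else {
        t <- t + gap
        times <- c(times, t)
        mult <- cfg$post_event_multiplier
        if (length(times) >= 5) break
      }
    }
    rec_n <- 0L
    new_rid <- function() {
      rec_n <<- rec_n + 1L
      sprintf("%s-R%03d", pid, rec_n)
    }
    for (et in times) {
      type <- sample(names(bp), 1,
                     prob = c(0.15, 0.05, 0.10, 0.10, 0.25, 0.35))
      b <- bp[[type]]
      onset <- max(1L, min(exp_days, round(et * DAYS_PER_YEAR)))
      serious <- stats::runif(1) < 0.95
      resolved <- stats::runif(1) < 0.7
      n_rec <- sample(1:2, 1)
      rid1 <- new_rid()
      ev <- thin_evidence(b$evidence(), cfg$evidence_completeness)
      evidence[[rid1]] <- ev
      for (k in seq_len(n_rec)) {
        ae_rows[[length(ae_rows) + 1]] <- list(
          record_id = if (k == 1) rid1 else new_rid(), patient_id = pid,
          preferred_term = b$pts[k], onset_day = onset + (k - 1L),
          onset_hour = NA_integer_,
          resolution_day = if (resolved) onset + 30L else NA_integer_,
          resolved = resolved, severity_grade = if (serious) 3L else 2L,
          serious = serious,
          dose_action = sample(c("none", "interrupted", "reduced"), 1,
                               prob = c(0.5, 0.4, 0.1)),
          anatomic_diagnosis = NA_character_, fatal = FALSE,
          nonadjudicated_aoe = TRUE)
      }
    }
    years <- exp_days / DAYS_PER_YEAR
    for (j in seq_len(stats::rpois(1, cfg$symptom_noise_rate * years))) {
      onset <- sample.int(exp_days, 1)
      ae_rows[[length(ae_rows) + 1]] <- list(
        record_id = new_rid(), patient_id = pid,
        preferred_term = sample(SYMPTOM_NOISE_PTS, 1), onset_day = onset,
        onset_hour = NA_integer_, resolution_day = onset + 7L,
        resolved = TRUE, severity_grade = sample(1:2, 1), serious = FALSE,
        dose_action = "none", anatomic_diagnosis = NA_character_,
        fatal = FALSE, nonadjudicated_aoe = TRUE)
    }
    for (j in seq_len(stats::rpois(1, cfg$nuisance_rate * years))) {
      onset <- sample.int(exp_days, 1)
      ae_rows[[length(ae_rows) + 1]] <- list(
        record_id = new_rid(), patient_id = pid,
        preferred_term = sample(NUISANCE_PTS, 1), onset_day = onset,
        onset_hour = NA_integer_, resolution_day = onset + 5L,
        resolved = TRUE, severity_grade = sample(1:2, 1), serious = FALSE,
        dose_action = "none", anatomic_diagnosis = NA_character_,
        fatal = FALSE, nonadjudicated_aoe = FALSE)
    }
    died <- stats::runif(1) < cfg$death_rate
    if (died) {
      rid <- new_rid()
      progression <- stats::runif(1) < 0.6
      ae_rows[[length(ae_rows) + 1]] <- list(
        record_id = rid, patient_id = pid,
        preferred_term = if (progression) "Disease progression" else "Sepsis",
        onset_day = exp_days, onset_hour = NA_integer_,
        resolution_day = NA_integer_, resolved = FALSE, severity_grade = 5L,
        serious = TRUE, dose_action = "withdrawn",
        anatomic_diagnosis = NA_character_, fatal = TRUE,
        nonadjudicated_aoe = FALSE)
      evidence[[rid]] <- evidence_package(death_specific_non_cv = TRUE)
      death_rows[[length(death_rows) + 1]] <- list(
        patient_id = pid, record_id = rid, death_day = exp_days,
        last_seen_alive_hours_before = 6,
        witnessed = FALSE, progression_attributed = progression)
    }
    pat_rows[[i]] <- list(
      patient_id = pid, cohort = cohort,
      age_years = 18L + sample.int(70, 1),
      sex = sample(c("male", "female"), 1, prob = c(0.53, 0.47)),
      risk_factors = format_risk_factors(rf),
      first_dose_day = 1L, last_contact_day = exp_days)
  }
  ds <- new_study_dataset(
    data.table::rbindlist(pat_rows),
    data.table::rbindlist(ae_rows),
    data.table::rbindlist(death_rows),
    evidence,
    provenance = list(generator = unclass(cfg)))
  ds
}

#' Run the full pipeline on a dataset
#'
#' Convenience driver: screen, group, adjudicate with the configured
#' committee, and return outcomes alongside the intermediate artifacts.
#'
#' @param ds an `aoe_study` dataset.
#' @param window_hours clustering window.
#' @param roster,flip_prob,seed committee parameters.
#' @param aoe_terms,cardiac_failure_terms term lists.
#' @return list with `screen`, `events`, `committee` (outcomes + traces) and
#'   the flattened `outcomes_dt`.
#' @export
aoe_pipeline <- function(ds, window_hours = 48, roster = committee_roster(),
                         flip_prob = 0, seed = 1,
                         aoe_terms = load_term_list(aoe_term_file("aoe_terms_604.txt")),
                         cardiac_failure_terms = load_term_list(aoe_term_file("cardiac_failure_terms.txt"))) {
  screen <- screen_adverse_events(ds, aoe_terms, cardiac_failure_terms)
  packages <- assemble_case_packages(screen, ds)
  events <- group_into_candidate_events(packages, window_hours)
  committee <- run_committee(events, ds, roster, flip_prob, seed)
  list(screen = screen, events = events, committee = committee,
       outcomes_dt = outcomes_table(committee$outcomes))
}
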