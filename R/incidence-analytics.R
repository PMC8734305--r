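# Trial-level summaries: patient-level AOE rates, exposure-adjusted
# incidence by yearly interval, time to onset, risk-factor strata, relative
# risk, dose-modification and resolution summaries.
#
# Reporting conventions: printed percentages round half away from zero to
# integers; months are days / 30.4375; patient-years are days / 365.25.

#' Flatten adjudication outcomes to a table
#'
#' @param outcomes list of `aoe_outcome` objects.
#' @return data.table with one row per adjudicated event.
#' @export
outcomes_table <- function(outcomes) {
  data.table::rbindlist(lapply(outcomes, function(o) {
    acts <- o$dose_actions[!is.na(o$dose_actions)]
    data.table::data.table(
      event_id = o$event_id, patient_id = o$patient_id,
      endpoint = o$endpoint, is_aoe = isTRUE(o$is_aoe),
      category = o$category %||% NA_character_,
      serious = isTRUE(o$serious), fatal = isTRUE(o$fatal),
      onset_day = o$onset_day,
      resolved = length(o$member_resolved) > 0 && all(o$member_resolved),
      worst_dose_action = worst_dose_action(o$dose_actions),
      panel_review = isTRUE(o$panel_review))
  }))
}

DOSE_ACTION_RANK <- c(none = 1, interrupted = 2, reduced = 3,
                      reduced_and_interrupted = 4,
                      interrupted_then_withdrawn = 5, withdrawn = 6)

worst_dose_action <- function(actions) {
  known <- actions[!is.na(actions)]
  if (!length(known)) return(NA_character_)
  names(which.max(DOSE_ACTION_RANK[known]))
}

qualifying_events <- function(outcomes_dt, serious_only = FALSE,
                              category = NULL) {
  q <- outcomes_dt[outcomes_dt$is_aoe == TRUE, ]
  if (serious_only) q <- q[q$serious == TRUE, ]
  if (!is.null(category)) q <- q[!is.na(q$category) & q$category == category, ]
  q
}

subset_patients <- function(patients, cohort = NULL) {
  if (is.null(cohort)) return(patients)
  keep <- patients[["cohort"]] %in% cohort   # computed outside `[` so the
  patients[keep, ]                           # cohort column cannot shadow it
}

incidence_result <- function(stratum, numerator, denominator,
                             patient_years = NA_real_) {
  stopifnot(numerator <= denominator)
  structure(list(
    stratum = stratum, numerator = numerator, denominator = denominator,
    patient_years = patient_years,
    rate_percent = if (denominator > 0) percent_of(numerator, denominator)
                   else NA_real_,
    rate_per_100py = if (!is.na(patient_years) && patient_years > 0)
                       100 * numerator / patient_years else NA_real_
  ), class = "aoe_incidence")
}

#' @export
print.aoe_incidence <- function(x, ...) {
  cat(sprintf("%s: %d/%d (%s%%)%s\n", x$stratum, x$numerator, x$denominator,
              x$rate_percent,
              if (!is.na(x$patient_years))
                sprintf("; %.1f per 100 PY over %.1f PY",
                        x$rate_per_100py, x$patient_years) else ""))
  invisible(x)
}

#' Patient-level AOE rates
#'
#' The numerator is the number of distinct patients with at least one
#' qualifying event; the denominator the patient population after cohort
#' filtering. `source = "adjudicated"` counts committee-confirmed AOEs from
#' `outcomes`; `source = "nonadjudicated"` counts the preferred-term-based
#' labels carried on the input AE records (the trial's original, broader
#' categorization — these are consumed as labels, never recomputed).
#'
#' @param outcomes list of `aoe_outcome`s (or an [outcomes_table()]).
#' @param patients the patients table.
#' @param records the adverse-events table (needed for non-adjudicated rates).
#' @param cohort optional cohort filter (e.g. `"CP-CML"`).
#' @param serious_only restrict to serious events.
#' @param category optional AOE category filter.
#' @param source `"adjudicated"` or `"nonadjudicated"`.
#' @return an `aoe_incidence` result.
#' @export
patient_level_rates <- function(outcomes, patients, records = NULL,
                                cohort = NULL, serious_only = FALSE,
                                category = NULL,
                                source = c("adjudicated", "nonadjudicated")) {
  source <- match.arg(source)
  pats <- subset_patients(patients, cohort)
  if (nrow(pats) == 0) stop("empty denominator after cohort filter")
  if (source == "adjudicated") {
    dt <- if (data.table::is.data.table(outcomes)) outcomes
          else outcomes_table(outcomes)
    q <- qualifying_events(dt, serious_only, category)
    pos <- unique(q$patient_id)
  } else {
    if (is.null(records)) stop("non-adjudicated rates need the AE records")
    r <- records[records$nonadjudicated_aoe == TRUE, ]
    if (serious_only) r <- r[r$serious == TRUE, ]
    pos <- unique(r$patient_id)
  }
  pos <- intersect(pos, pats$patient_id)
  incidence_result(
    stratum = paste0(source, if (serious_only) "/serious" else "/any",
                     if (!is.null(cohort)) paste0("/", paste(cohort, collapse = "+")) else ""),
    numerator = length(pos), denominator = nrow(pats))
}

#' Exposure-adjusted incidence of first events
#'
#' Rate = (number of first qualifying events in the interval) /
#' (patient-years of exposure in the interval) x 100. A patient's exposure
#' accrues from first dose until the first qualifying event, treatment
#' end/death, or (with `censor = "last_contact"`) last contact. Patients
#' with a first event in an earlier interval are excluded from later
#' intervals.
#'
#' @param outcomes adjudication outcomes (list or table).
#' @param patients patients table with `first_dose_day`, `last_contact_day`.
#' @param interval optional `c(start_year, end_year)` window measured from
#'   first dose; NULL means the whole observation span.
#' @param serious_only,category event filters as in [patient_level_rates()].
#' @param censor exposure censoring rule.
#' @return an `aoe_incidence` result with `patient_years` filled in.
#' @export
exposure_adjusted_incidence <- function(outcomes, patients, interval = NULL,
                                        serious_only = FALSE, category = NULL,
                                        censor = c("event_treatment_death",
                                                   "last_contact")) {
  censor <- match.arg(censor)
  dt <- if (data.table::is.data.table(outcomes)) outcomes
        else outcomes_table(outcomes)
  q <- qualifying_events(dt, serious_only, category)
  first_event <- tapply(q$onset_day, q$patient_id, min)
  lo <- if (is.null(interval)) 0 else interval[1] * DAYS_PER_YEAR
  hi <- if (is.null(interval)) Inf else interval[2] * DAYS_PER_YEAR
  n_events <- 0L
  py_days <- 0
  for (i in seq_len(nrow(patients))) {
    pid <- patients$patient_id[i]
    exp_days <- patients$last_contact_day[i] - patients$first_dose_day[i] + 1
    fe <- if (pid %in% names(first_event)) first_event[[pid]] else NA_real_
    fe_rel <- if (!is.na(fe)) fe - patients$first_dose_day[i] + 1 else Inf
    end_at_risk <- min(exp_days, fe_rel)
    if (censor == "last_contact") end_at_risk <- min(exp_days, fe_rel)
    if (fe_rel <= lo) next                      # prior event: excluded
    if (end_at_risk <= lo) next                 # never at risk in interval
    contrib <- min(end_at_risk, hi) - lo
    py_days <- py_days + contrib
    if (is.finite(fe_rel) && fe_rel > lo && fe_rel <= hi)
      n_events <- n_events + 1L
  }
  if (py_days <= 0) stop("zero patient-years in interval")
  incidence_result(
    stratum = if (is.null(interval)) "overall"
              else sprintf("year %g-%g", interval[1], interval[2]),
    numerator = n_events, denominator = nrow(patients),
    patient_years = days_to_years(py_days))
}

#' Time to onset of the first qualifying event
#'
#' Months are days / 30.4375; the summary reports the per-patient first
#' event, rounded to one decimal as printed in trial reports.
#'
#' @param outcomes adjudication outcomes.
#' @param patients optional patients table for cohort filtering.
#' @param category,cohort filters.
#' @return list with `n`, `median_months`, `min_months`, `max_months`
#'   (empty summary with `n = 0` when no patient qualifies).
#' @export
time_to_first_event_summary <- function(outcomes, patients = NULL,
                                        category = NULL, cohort = NULL) {
  dt <- if (data.table::is.data.table(outcomes)) outcomes
        else outcomes_table(outcomes)
  q <- qualifying_events(dt, category = category)
  if (!is.null(cohort) && !is.null(patients)) {
    keep <- patients$patient_id[patients$cohort %in% cohort]
    q <- q[q$patient_id %in% keep, ]
  }
  if (nrow(q) == 0)
    return(list(n = 0L, median_months = NA_real_, min_months = NA_real_,
                max_months = NA_real_))
  first <- tapply(q$onset_day, q$patient_id, min)
  months <- days_to_months(as.numeric(first))
  list(n = length(months),
       median_months = round_half_away(stats::median(months), 1),
       min_months = round_half_away(min(months), 1),
       max_months = round_half_away(max(months), 1))
}

#' Patient-level AOE rates by number of baseline risk factors
#'
#' Strata are 0, 1-2 and >= 3 of the six tracked factors (arterial
#' hypertension, hypercholesterolemia, obesity, diabetes mellitus,
#' non-ischemic cardiac history, ischemic history).
#'
#' @param outcomes adjudication outcomes.
#' @param patients patients table.
#' @param serious_only restrict numerators to serious AOEs.
#' @return list of `aoe_incidence` results keyed `"0"`, `"1-2"`, `">=3"`.
#' @export
risk_factor_strata <- function(outcomes, patients, serious_only = FALSE) {
  dt <- if (data.table::is.data.table(outcomes)) outcomes
        else outcomes_table(outcomes)
  q <- qualifying_events(dt, serious_only)
  pos <- unique(q$patient_id)
  nf <- risk_factor_count(patients$risk_factors)
  stratum <- cut(nf, breaks = c(-1, 0, 2, 6), labels = c("0", "1-2", ">=3"))
  out <- list()
  for (s in levels(stratum)) {
    ids <- patients$patient_id[stratum == s]
    out[[s]] <- incidence_result(
      stratum = paste0("risk factors ", s),
      numerator = length(intersect(pos, ids)),
      denominator = length(ids))
  }
  out
}

#' Relative risk of serious AOE by baseline risk category
#'
#' 2x2 analysis restricted to patients whose baseline categories are all
#' available: RR = (a/(a+b)) / (c/(c+d)) with a 95% CI from the log-normal
#' approximation. A zero cell in a denominator arm yields an undefined CI
#' and a continuity-corrected (+0.5) point estimate.
#'
#' @param outcomes adjudication outcomes.
#' @param patients patients table.
#' @param factor one of the six risk-factor names.
#' @return list with the 2x2 counts, `rr`, `ci_low`, `ci_high`.
#' @export
relative_risk_serious_aoe <- function(outcomes, patients, factor) {
  stopifnot(factor %in% RISK_FACTORS)
  dt <- if (data.table::is.data.table(outcomes)) outcomes
        else outcomes_table(outcomes)
  q <- qualifying_events(dt, serious_only = TRUE)
  pos <- unique(q$patient_id)
  has <- vapply(patients$risk_factors,
                function(s) factor %in% parse_risk_factors(s), logical(1))
  out <- patients$patient_id %in% pos
  a <- sum(has & out); b <- sum(has & !out)
  c_ <- sum(!has & out); d <- sum(!has & !out)
  if (a == 0 || c_ == 0) {
    rr <- ((a + 0.5) / (a + b + 0.5)) / ((c_ + 0.5) / (c_ + d + 0.5))
    return(list(a = a, b = b, c = c_, d = d, rr = rr,
                ci_low = NA_real_, ci_high = NA_real_))
  }
  rr <- (a / (a + b)) / (c_ / (c_ + d))
  se <- sqrt(1 / a - 1 / (a + b) + 1 / c_ - 1 / (c_ + d))
  list(a = a, b = b, c = c_, d = d, rr = rr,
       ci_low = exp(log(rr) - 1.96 * se),
       ci_high = exp(log(rr) + 1.96 * se))
}

DOSE_SUMMARY_ROWS <- c("no_dose_modification", "interrupted_only",
                       "reduced_only", "reduced_and_interrupted",
                       "interrupted_then_withdrawn", "withdrawn",
                       "not_applicable_unknown")

#' Per-patient worst dose action after AOEs
#'
#' Each patient with at least one qualifying event contributes their most
#' severe action over all qualifying events, under the severity order
#' withdrawn > reduced+interrupted > reduced only > interrupted only > none;
#' interruption followed by withdrawal is its own row and counts as a
#' discontinuation. Unknown actions land in "not applicable/unknown".
#'
#' @param outcomes adjudication outcomes.
#' @param serious_only restrict to serious events.
#' @return list with `counts` (named integer vector over the table rows),
#'   `n_patients` and `percents`.
#' @export
dose_modification_summary <- function(outcomes, serious_only = FALSE) {
  dt <- if (data.table::is.data.table(outcomes)) outcomes
        else outcomes_table(outcomes)
  q <- qualifying_events(dt, serious_only)
  if (nrow(q) == 0)
    return(list(counts = stats::setNames(integer(length(DOSE_SUMMARY_ROWS)),
                                         DOSE_SUMMARY_ROWS),
                n_patients = 0L, percents = NULL))
  worst <- tapply(q$worst_dose_action, q$patient_id, function(acts) {
    known <- acts[!is.na(acts)]
    if (!length(known)) NA_character_
    else names(which.max(DOSE_ACTION_RANK[known]))
  })
  row_of <- function(a) {
    if (is.na(a)) "not_applicable_unknown"
    else switch(a, none = "no_dose_modification",
                interrupted = "interrupted_only", reduced = "reduced_only",
                reduced_and_interrupted = "reduced_and_interrupted",
                interrupted_then_withdrawn = "interrupted_then_withdrawn",
                withdrawn = "withdrawn")
  }
  rows <- vapply(worst, row_of, character(1))
  counts <- table(factor(rows, levels = DOSE_SUMMARY_ROWS))
  n <- length(rows)
  list(counts = stats::setNames(as.integer(counts), DOSE_SUMMARY_ROWS),
       n_patients = n,
       percents = stats::setNames(percent_of(as.integer(counts), n),
                                  DOSE_SUMMARY_ROWS),
       discontinued = sum(rows %in% c("withdrawn", "interrupted_then_withdrawn")),
       discontinued_percent = percent_of(
         sum(rows %in% c("withdrawn", "interrupted_then_withdrawn")), n))
}

#' Resolution of adjudicated AOEs
#'
#' An event is resolved iff all its member records resolved. Patients with a
#' single qualifying event count as resolved when that event resolved;
#' patients with multiple events count only when all of them resolved.
#'
#' @param outcomes adjudication outcomes.
#' @return list with single-event and multi-event numerators, denominators
#'   and percentages.
#' @export
resolution_summary <- function(outcomes) {
  dt <- if (data.table::is.data.table(outcomes)) outcomes
        else outcomes_table(outcomes)
  q <- qualifying_events(dt)
  n_ev <- tapply(q$event_id, q$patient_id, length)
  all_res <- tapply(q$resolved, q$patient_id, all)
  single <- names(n_ev)[n_ev == 1]
  multi <- names(n_ev)[n_ev > 1]
  list(
    single_n = length(single),
    single_resolved = sum(unlist(all_res[single])),
    single_percent = if (length(single))
      percent_of(sum(unlist(all_res[single])), length(single)) else NA_real_,
    multi_n = length(multi),
    multi_all_resolved = sum(unlist(all_res[multi])),
    multi_percent = if (length(multi))
      percent_of(sum(unlist(all_res[multi])), length(multi)) else NA_real_)
}

#' Baseline characteristics summary
#'
#' Cohort sizes, age and sex distribution, and baseline risk-factor
#' prevalences for the fields carried in the data model.
#'
#' @param patients patients table.
#' @return list of summary components.
#' @export
baseline_summary <- function(patients) {
  nf <- lapply(RISK_FACTORS, function(f)
    sum(vapply(patients$risk_factors,
               function(s) f %in% parse_risk_factors(s), logical(1))))
  names(nf) <- RISK_FACTORS
  n <- nrow(patients)
  list(
    n = n,
    cohort_sizes = table(factor(patients$cohort, levels = COHORTS)),
    median_age = stats::median(patients$age_years),
    age_range = range(patients$age_years),
    female_n = sum(patients$sex == "female"),
    female_percent = percent_of(sum(patients$sex == "female"), n),
    risk_factor_counts = unlist(nf),
    risk_factor_percents = percent_of(unlist(nf), n))
}
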