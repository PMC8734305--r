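# analytics are exercised against hand-built outcome tables; the calibrated
# fixture end-to-end checks live in test-acceptance.R

fake_outcomes <- function(df) {
  defaults <- data.table::data.table(
    event_id = sprintf("E%02d", seq_len(nrow(df))), endpoint = "MI_type1",
    is_aoe = TRUE, category = "cardiovascular", serious = TRUE, fatal = FALSE,
    onset_day = 100, resolved = TRUE, worst_dose_action = "none",
    panel_review = FALSE)
  for (col in names(df)) defaults[[col]] <- df[[col]]
  defaults
}

fake_patients <- function(n, cohort = "CP-CML", rf = "", exposure = 365) {
  data.table::data.table(
    patient_id = sprintf("P%03d", seq_len(n)), cohort = cohort,
    age_years = 60L, sex = "male", risk_factors = rf,
    first_dose_day = 1L, last_contact_day = as.integer(exposure))
}

test_that("printed percentages use half-away-from-zero rounding", {
  expect_equal(percent_of(2, 80), 3)     # 2.5 -> 3, the convention-fixing case
  expect_equal(percent_of(78, 449), 17)
  expect_equal(percent_of(111, 449), 25)
  expect_equal(round_half_away(-2.5), -3)
  expect_equal(round_half_away(14.05, 1), 14.1)
  # property: matches exact integer arithmetic on a grid
  for (num in 0:60) for (den in c(35, 43, 78, 80)) {
    expected <- (100 * num) %/% den + (2 * ((100 * num) %% den) >= den)
    expect_equal(percent_of(num, den), expected, info = paste(num, den))
  }
})

test_that("patient-level rates count distinct patients with qualifying events", {
  pats <- fake_patients(100)
  out <- fake_outcomes(data.table::data.table(
    patient_id = c("P001", "P001", "P002", "P003"),
    serious = c(TRUE, FALSE, FALSE, TRUE)))
  any_rate <- patient_level_rates(out, pats)
  expect_equal(any_rate$numerator, 3)
  expect_equal(any_rate$rate_percent, 3)
  ser <- patient_level_rates(out, pats, serious_only = TRUE)
  expect_equal(ser$numerator, 2)
  # serious subset of any, in every stratum
  expect_lte(ser$numerator, any_rate$numerator)
  zero <- patient_level_rates(fake_outcomes(
    data.table::data.table(patient_id = character())), pats)
  expect_equal(zero$rate_percent, 0)
  expect_error(patient_level_rates(out, pats, cohort = "Ph+ALL"),
               "empty denominator")
})

test_that("exposure-adjusted incidence matches the closed form", {
  # 4 first events over 50 patient-years -> 8.0 per 100 PY
  pats <- fake_patients(10, exposure = round(5 * 365.25))
  out <- fake_outcomes(data.table::data.table(
    patient_id = sprintf("P%03d", 1:4),
    onset_day = round(5 * 365.25)))   # events at the very end: full exposure
  r <- exposure_adjusted_incidence(out, pats)
  expect_equal(r$numerator, 4)
  expect_equal(r$patient_years, 50, tolerance = 0.01)
  expect_equal(r$rate_per_100py, 8, tolerance = 0.01)
  # no events, any exposure -> 0
  r0 <- exposure_adjusted_incidence(
    fake_outcomes(data.table::data.table(patient_id = character())), pats)
  expect_equal(r0$rate_per_100py, 0)
})

test_that("yearly intervals exclude patients with prior events", {
  pats <- fake_patients(3, exposure = round(2 * 365.25))
  out <- fake_outcomes(data.table::data.table(
    patient_id = c("P001", "P002"),
    onset_day = c(100, round(1.5 * 365.25))))  # year-1 and year-2 events
  y1 <- exposure_adjusted_incidence(out, pats, interval = c(0, 1))
  y2 <- exposure_adjusted_incidence(out, pats, interval = c(1, 2))
  expect_equal(y1$numerator, 1)
  expect_equal(y2$numerator, 1)
  # patient 1 contributes ~100 days to year 1 and nothing to year 2
  expect_equal(y1$patient_years, (100 + 365.25 + 365.25) / 365.25,
               tolerance = 0.01)
  expect_equal(y2$patient_years, (0.5 + 1) * 365.25 / 365.25,
               tolerance = 0.01)
  # first-event numerators over intervals sum to total patients with events
  expect_equal(y1$numerator + y2$numerator, 2)
})

test_that("time-to-onset summaries use months = days / 30.4375", {
  out <- fake_outcomes(data.table::data.table(
    patient_id = c("P1", "P2", "P3"),
    onset_day = round(c(3, 6, 9) * 30.4375)))
  s <- time_to_first_event_summary(out)
  expect_equal(s$median_months, 6)
  one <- fake_outcomes(data.table::data.table(
    patient_id = "P1", onset_day = round(14.1 * 30.4375)))
  s1 <- time_to_first_event_summary(one)
  expect_equal(s1$median_months, 14.1)
  expect_equal(s1$min_months, 14.1)
  expect_equal(s1$max_months, 14.1)
  empty <- time_to_first_event_summary(fake_outcomes(
    data.table::data.table(patient_id = character())))
  expect_equal(empty$n, 0)
})

test_that("risk-factor strata split at 0, 1-2 and >= 3 factors", {
  pats <- fake_patients(6)
  pats$risk_factors <- c("", "arterial_hypertension",
                         "arterial_hypertension;diabetes_mellitus",
                         "arterial_hypertension;diabetes_mellitus;obesity",
                         "arterial_hypertension;hypercholesterolemia;obesity;diabetes_mellitus",
                         "")
  out <- fake_outcomes(data.table::data.table(patient_id = c("P003", "P004")))
  rs <- risk_factor_strata(out, pats)
  expect_equal(rs[["0"]]$denominator, 2)
  expect_equal(rs[["1-2"]]$denominator, 2)
  expect_equal(rs[[">=3"]]$denominator, 2)
  expect_equal(rs[["1-2"]]$numerator, 1)   # P003 has two factors
  expect_equal(rs[[">=3"]]$numerator, 1)   # P004 has three
})

test_that("relative risk matches hand calculation and handles zero cells", {
  pats <- fake_patients(200)
  pats$risk_factors <- rep(c("ischemic_history", ""), each = 100)
  # a=20 exposed cases, c=10 unexposed cases
  out <- fake_outcomes(data.table::data.table(
    patient_id = sprintf("P%03d", c(1:20, 101:110))))
  rr <- relative_risk_serious_aoe(out, pats, "ischemic_history")
  expect_equal(rr$a, 20); expect_equal(rr$c, 10)
  expect_equal(rr$rr, 2)
  se <- sqrt(1 / 20 - 1 / 100 + 1 / 10 - 1 / 100)
  expect_equal(rr$ci_low, exp(log(2) - 1.96 * se))
  expect_equal(rr$ci_high, exp(log(2) + 1.96 * se))
  # symmetry: equal arms give RR 1
  out_sym <- fake_outcomes(data.table::data.table(
    patient_id = sprintf("P%03d", c(1:10, 101:110))))
  expect_equal(relative_risk_serious_aoe(out_sym, pats, "ischemic_history")$rr, 1)
  # zero cell: undefined CI, continuity-corrected point estimate
  out_zero <- fake_outcomes(data.table::data.table(
    patient_id = sprintf("P%03d", 1:10)))
  rz <- relative_risk_serious_aoe(out_zero, pats, "ischemic_history")
  expect_true(is.na(rz$ci_low))
  expect_gt(rz$rr, 1)
})

test_that("dose-modification summary takes the per-patient worst action", {
  out <- fake_outcomes(data.table::data.table(
    patient_id = c("P1", "P1", "P2", "P3"),
    worst_dose_action = c("interrupted", "withdrawn", "none", NA)))
  dm <- dose_modification_summary(out)
  expect_equal(unname(dm$counts["withdrawn"]), 1)          # P1's worst
  expect_equal(unname(dm$counts["no_dose_modification"]), 1)
  expect_equal(unname(dm$counts["not_applicable_unknown"]), 1)
  expect_equal(dm$n_patients, 3)
  expect_equal(dm$discontinued, 1)
})

test_that("resolution requires all records and all events", {
  out <- fake_outcomes(data.table::data.table(
    patient_id = c("P1", "P2", "P2", "P3", "P3"),
    resolved = c(TRUE, TRUE, TRUE, TRUE, FALSE)))
  rs <- resolution_summary(out)
  expect_equal(rs$single_n, 1)
  expect_equal(rs$single_resolved, 1)
  expect_equal(rs$multi_n, 2)
  expect_equal(rs$multi_all_resolved, 1)   # P3 has one unresolved event
})

test_that("baseline summary covers cohorts, age, sex and prevalences", {
  pats <- fake_patients(3)
  pats$sex <- "female"
  pats$age_years <- c(50L, 59L, 70L)
  pats$risk_factors <- c("arterial_hypertension", "arterial_hypertension", "")
  b <- baseline_summary(pats)
  expect_equal(b$female_percent, 100)
  expect_equal(b$median_age, 59)
  expect_equal(unname(b$risk_factor_counts["arterial_hypertension"]), 2)
  expect_equal(unname(b$cohort_sizes["CP-CML"]), 3)
})
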