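test_that("generation is reproducible and per-patient streams are stable", {
  cfg <- generator_config(n_patients = 25, seed = 77)
  a <- quiet(generate_trial(cfg))
  b <- quiet(generate_trial(cfg))
  expect_identical(a$patients, b$patients)
  expect_identical(a$adverse_events, b$adverse_events)
  expect_identical(a$deaths, b$deaths)
  # adding patients never perturbs existing ones
  big <- quiet(generate_trial(generator_config(n_patients = 40, seed = 77)))
  expect_identical(big$patients[1:25, ], a$patients)
  small_p1 <- a$adverse_events[a$adverse_events$patient_id == "S00001", ]
  big_p1 <- big$adverse_events[big$adverse_events$patient_id == "S00001", ]
  expect_identical(small_p1, big_p1)
})

test_that("invalid configurations fail fast", {
  expect_error(generator_config(cohort_fractions = c(1, 1, 1, 1)), "sum to 1")
  expect_error(generator_config(risk_factor_prevalences = c(
    arterial_hypertension = 1.2)), "prevalences")
  expect_error(generator_config(evidence_completeness = 2), "completeness")
})

test_that("risk-factor prevalences hit their targets at scale", {
  cfg <- generator_config(n_patients = 8000, seed = 31,
                          aoe_hazard = list(baseline = 0, factor_effects = c(),
                                            decay = 1),
                          symptom_noise_rate = 0, nuisance_rate = 0,
                          death_rate = 0)
  ds <- quiet(generate_trial(cfg))
  p_hat <- mean(vapply(ds$patients$risk_factors, function(s)
    "arterial_hypertension" %in% aoe:::parse_risk_factors(s), logical(1)))
  se <- sqrt(0.53 * 0.47 / 8000)
  expect_lt(abs(p_hat - 0.53), 3 * se)
  # cohort fractions similarly
  frac_cp <- mean(ds$patients$cohort == "CP-CML")
  expect_lt(abs(frac_cp - 270 / 449), 3 * sqrt(0.6 * 0.4 / 8000))
})

test_that("hazard decay shapes the yearly incidence profile", {
  base_cfg <- function(decay, seed) generator_config(
    n_patients = 2500, seed = seed,
    risk_factor_prevalences = c(arterial_hypertension = 0),
    aoe_hazard = list(baseline = 0.25,
                      factor_effects = c(arterial_hypertension = 1),
                      decay = decay),
    symptom_noise_rate = 0, nuisance_rate = 0, death_rate = 0,
    mean_exposure_months = 48)
  yearly <- function(ds) {
    # first true-event rate per interval, straight from the latent records
    out <- quiet(aoe_pipeline(ds))
    vapply(list(c(0, 1), c(1, 2)), function(iv)
      exposure_adjusted_incidence(out$outcomes_dt, ds$patients,
                                  interval = iv)$rate_per_100py, numeric(1))
  }
  flat <- yearly(quiet(generate_trial(base_cfg(1, 13))))
  # constant hazard: year 1 and year 2 agree within Monte-Carlo tolerance
  expect_lt(abs(flat[1] - flat[2]) / flat[1], 0.35)
  decayed <- yearly(quiet(generate_trial(base_cfg(0.4, 13))))
  expect_gt(decayed[1], decayed[2])   # decaying hazard: year 2 below year 1
})

test_that("the pipeline closes over random generator configs", {
  set.seed(99)
  for (k in 1:12) {
    cfg <- generator_config(
      n_patients = sample(5:15, 1),
      aoe_hazard = list(baseline = runif(1, 0.05, 0.5),
                        factor_effects = c(arterial_hypertension = runif(1, 1, 2)),
                        decay = runif(1, 0.5, 1)),
      symptom_noise_rate = runif(1, 0, 0.5),
      nuisance_rate = runif(1, 0, 4),
      evidence_completeness = runif(1, 0.5, 1),
      death_rate = runif(1, 0, 0.2),
      seed = sample.int(1e6, 1))
    ds <- quiet(generate_trial(cfg))
    expect_no_error({
      pl <- quiet(aoe_pipeline(ds))
      patient_level_rates(pl$outcomes_dt, ds$patients)
      if (any(pl$outcomes_dt$is_aoe))
        time_to_first_event_summary(pl$outcomes_dt)
    })
  }
})

test_that("screened rate exceeds adjudicated rate, which recovers the true rate", {
  cfg <- generator_config(n_patients = 3000, seed = 55,
                          aoe_hazard = list(
                            baseline = 0.08,
                            factor_effects = c(arterial_hypertension = 1),
                            decay = 1),
                          risk_factor_prevalences = c(arterial_hypertension = 0),
                          symptom_noise_rate = 0.3, nuisance_rate = 1,
                          evidence_completeness = 1, death_rate = 0)
  ds <- quiet(generate_trial(cfg))
  pl <- quiet(aoe_pipeline(ds))
  adj <- patient_level_rates(pl$outcomes_dt, ds$patients)
  scr <- patient_level_rates(pl$outcomes_dt, ds$patients,
                             records = ds$adverse_events,
                             source = "nonadjudicated")
  # the broad screen label is strictly more inclusive than adjudication
  expect_gt(scr$numerator, adj$numerator)
  # adjudication recovers the latent true-event patients: every adjudicated
  # patient carries a true event record and vice versa (completeness = 1)
  true_pat <- unique(ds$adverse_events$patient_id[
    ds$adverse_events$nonadjudicated_aoe &
      !ds$adverse_events$preferred_term %in%
        c("Angina pectoris", "Chest pain", "Non-cardiac chest pain",
          "Chest discomfort", "Intermittent claudication",
          "Peripheral coldness")])
  adj_pat <- unique(pl$outcomes_dt$patient_id[pl$outcomes_dt$is_aoe])
  expect_setequal(adj_pat, true_pat)
})

test_that("the Table-12 transcription carries the published accounting", {
  t12 <- table12_fixture()
  expect_equal(nrow(t12), 11)
  with_hist <- nzchar(t12$cv_history) | nzchar(t12$cv_risk_factors)
  expect_equal(sum(with_hist), 9)
  expect_equal(sum(t12$status == "ALL"), 2)
})
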