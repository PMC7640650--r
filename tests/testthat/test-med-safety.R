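cfg <- staging_config()
form <- default_formulary()

test_that("classification is normalized, deterministic and total", {
  expect_equal(classify_medication("Furosemide", form)$drug_class,
               "diuretic")
  expect_true(classify_medication("Furosemide", form)$may_cause_aki)
  expect_equal(classify_medication("  IBUPROFEN ", form)$drug_class,
               "nsaid")
  unknown <- classify_medication("acetaminophen", form)
  expect_equal(unknown$drug_class, "other")
  expect_false(unknown$may_cause_aki)
  expect_false(unknown$renally_cleared)
})

test_that("formulary files validate their entries", {
  bad <- withr::local_tempfile(fileext = ".json")
  writeLines('{"x": {"risk_class": "nsaid", "may_cause_aki": false,
               "renally_cleared": false}}', bad)
  expect_error(read_formulary(bad), "no true flag")
  writeLines('{"x": {"risk_class": "vitamin", "may_cause_aki": true,
               "renally_cleared": false}}', bad)
  expect_error(read_formulary(bad), "risk_class")
})

test_that("active_risk_medications applies the activity interval and risk flag", {
  orders <- rbind(
    mk_med("A", "ibuprofen", -1),                      # active risk med
    mk_med("A", "furosemide", -2, dc_days = -0.04),    # discontinued
    mk_med("A", "acetaminophen", -1),                  # not a risk med
    mk_med("A", "vancomycin", 1))                      # ordered later
  act <- active_risk_medications(orders, at_d(0), form)
  expect_equal(act$drug_name, "ibuprofen")
  expect_equal(act$drug_class, "nsaid")
  # discontinuation boundary: at == discontinued_at means inactive
  o <- mk_med("A", "ibuprofen", -1, dc_days = 0)
  expect_equal(nrow(active_risk_medications(o, at_d(0), form)), 0L)
})

test_that("order checks fire only in-episode, in-window, for risk drugs", {
  epi <- list(in_episode = TRUE, onset_at = at_d(0),
              max_alerted_stage = 2L, episode_index = 1L)
  w <- check_medication_order(mk_med("A", "ibuprofen", 1), epi, form, cfg)
  expect_equal(w$aki_stage_at_order, 2L)
  expect_equal(w$drug_class, "nsaid")
  expect_false(w$overridden)
  expect_equal(w$raised_at, at_d(1))

  expect_null(check_medication_order(mk_med("A", "ibuprofen", 2.1),
                                     epi, form, cfg))  # 50.4 h > 48 h
  w48 <- check_medication_order(mk_med("A", "ibuprofen", 2), epi, form, cfg)
  expect_equal(w48$onset_at, at_d(0))  # exactly 48 h still warns
  expect_null(check_medication_order(mk_med("A", "acetaminophen", 1), epi,
                                     form, cfg))
  expect_null(check_medication_order(
    mk_med("A", "ibuprofen", 1),
    list(in_episode = FALSE, onset_at = at_d(0), max_alerted_stage = 0L,
         episode_index = 0L), form, cfg))
})

test_that("no warning is ever emitted without an open episode", {
  sim <- generate_cohort(sim_config(n_patients = 40, aki_incidence = 0,
                                    seed = 21))
  expect_equal(nrow(detect_warnings(sim$cohort, NULL, form, cfg)), 0L)
})

test_that("cohort warnings equal the brute-force pair enumeration", {
  sim <- generate_cohort(sim_config(n_patients = 80, aki_incidence = 0.6,
                                    p_risk_order_post_onset = 0.6,
                                    measurement_noise_cv = 0.05, seed = 13))
  det <- detect_alerts(sim$cohort, cfg, form)
  got <- detect_warnings(sim$cohort, det, form, cfg)
  want <- oracle_warnings(sim$cohort$meds, det$episodes, det$alerts, form,
                          cfg)
  key <- function(d, t) paste(d$patient_id, as.numeric(t), d$drug_name)
  expect_setequal(key(got, got$ordered_at), key(want, want$ordered_at))
  got_o <- got[order(key(got, got$ordered_at)), ]
  want_o <- want[order(key(want, want$ordered_at)), ]
  expect_equal(got_o$aki_stage_at_order, want_o$stage)
})

test_that("window limits behave: 0 h warns only at onset, huge window spans the episode", {
  labs <- rbind(mk_lab("A", 100, 0), mk_lab("A", 160, 1),
                mk_lab("A", 165, 3), mk_lab("A", 166, 5))
  meds <- rbind(mk_med("A", "ibuprofen", 1),     # exactly at onset
                mk_med("A", "naproxen", 4))      # 72 h after onset
  co <- aki_cohort(labs = labs, meds = meds)
  cfg0 <- staging_config(med_warning_window_hours = 1e-9)
  w0 <- detect_warnings(co, NULL, form, cfg0)
  expect_equal(w0$drug_name, "ibuprofen")
  cfg_any <- staging_config(warn_any_time_in_episode = TRUE)
  w_any <- detect_warnings(co, NULL, form, cfg_any)
  expect_setequal(w_any$drug_name, c("ibuprofen", "naproxen"))
})
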