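form <- default_formulary()

test_that("fluid balance is intake minus output over a half-open interval", {
  fl <- rbind(mk_fluid("A", "intake_iv", 1500, 0.1),
              mk_fluid("A", "intake_oral", 500, 0.2),
              mk_fluid("A", "output_urine", 1200, 0.3),
              mk_fluid("A", "output_other", 100, 0.99),
              mk_fluid("A", "intake_iv", 999, 1.0))  # at end: excluded
  expect_equal(fluid_balance(fl, at_d(0), at_d(1)), 700)
  expect_equal(fluid_balance(fl, at_d(2), at_d(3)), 0)
  out_only <- mk_fluid("A", "output_urine", 1500, 0.5)
  expect_equal(fluid_balance(out_only, at_d(0), at_d(1)), -1500)
})

test_that("interval fluid balances add up over a partition of the window", {
  sim <- generate_cohort(sim_config(n_patients = 4, include_supporting = TRUE,
                                    seed = 8))
  fl <- sim$cohort$fluids
  whole <- fluid_balance(fl, at_d(-10), at_d(50))
  cuts <- at_d(seq(-10, 50, by = 2.5))
  parts <- vapply(seq_len(length(cuts) - 1), function(i)
    fluid_balance(fl, cuts[i], cuts[i + 1]), numeric(1))
  expect_equal(sum(parts), whole)
})

test_that("urine output totals and weight-indexed rates", {
  fl <- rbind(mk_fluid("A", "output_urine", 300, 0.1),
              mk_fluid("A", "output_urine", 420, 0.3),
              mk_fluid("A", "intake_iv", 1000, 0.2))
  r <- urine_output_rate(fl, at_d(0), at_d(0.5), weight_kg = 60)
  expect_equal(r$total_ml, 720)
  expect_equal(r$rate_ml_kg_h, 720 / 60 / 12)
  r2 <- urine_output_rate(fl, at_d(0), at_d(0.5))
  expect_equal(r2$total_ml, 720)
  expect_true(is.na(r2$rate_ml_kg_h))
  expect_equal(urine_output_rate(empty_cohort_fluids(), at_d(0),
                                 at_d(0.5))$total_ml, 0)
  expect_error(urine_output_rate(fl, at_d(0), at_d(0.5), weight_kg = -1),
               "positive")
  expect_error(urine_output_rate(fl, at_d(1), at_d(1)), "duration")
})

test_that("the dashboard aggregates every panel and keeps acknowledged alerts", {
  labs <- rbind(mk_lab("A", 100, 0), mk_lab("A", 160, 1),
                mk_lab("A", 170, 2),
                mk_lab("A", 12, 1, analyte = "wbc"),
                mk_lab("A", 140, 1, analyte = "sodium"),
                mk_lab("A", 9.1, 1, analyte = "urea"))
  ev <- aki_cohort(labs = labs,
                   meds = rbind(mk_med("A", "ibuprofen", 0.5),
                                mk_med("A", "digoxin", 0.5),
                                mk_med("A", "vancomycin", 0.5)),
                   fluids = rbind(mk_fluid("A", "intake_iv", 500, 1.2),
                                  mk_fluid("A", "output_urine", 300, 1.3)),
                   vitals = data.frame(patient_id = "A", encounter_id = "E1",
                                       kind = "heart_rate", value = 88,
                                       recorded_at = at_d(1),
                                       stringsAsFactors = FALSE),
                   encounters = mk_enc("A"))
  alerts <- process_patient(ev, staging_config())$alerts
  alerts[1, ] <- acknowledge_alert(alerts[1, ], at_d(1.5))
  dash <- build_dashboard(ev, alerts, form, as_of = at_d(2))
  expect_equal(nrow(dash$alert_history), 1L)
  expect_equal(dash$alert_history$status, "acknowledged")
  expect_equal(nrow(dash$creatinine_trend), 3L)
  expect_equal(nrow(dash$urea_trend), 1L)
  expect_equal(nrow(dash$electrolyte_trends$sodium), 1L)
  # vancomycin carries both flags and appears in both panels
  expect_setequal(dash$meds_may_worsen_aki$drug_name,
                  c("ibuprofen", "vancomycin"))
  expect_setequal(dash$meds_renally_cleared$drug_name,
                  c("digoxin", "vancomycin"))
  expect_equal(nrow(dash$infection_markers$wbc_trend), 1L)
  expect_equal(nrow(dash$iv_therapies), 1L)
  expect_equal(nrow(dash$visit_history), 1L)
  expect_equal(sum(dash$fluid_balance_by_interval$net_ml), 200)
  expect_equal(sum(dash$urine_output_by_interval$total_ml), 300)
})

test_that("the dashboard is a pure function of events at or before as_of", {
  labs <- rbind(mk_lab("A", 100, 0), mk_lab("A", 160, 1))
  ev1 <- aki_cohort(labs = labs, encounters = mk_enc("A"))
  alerts1 <- process_patient(ev1, staging_config())$alerts
  d1 <- build_dashboard(ev1, alerts1, form, as_of = at_d(1.5))

  labs2 <- rbind(labs, mk_lab("A", 300, 2),
                 mk_lab("A", 15, 3, analyte = "wbc"))
  ev2 <- aki_cohort(labs = labs2,
                    meds = mk_med("A", "ibuprofen", 2.5),
                    encounters = mk_enc("A"))
  alerts2 <- process_patient(ev2, staging_config())$alerts
  d2 <- build_dashboard(ev2, alerts2, form, as_of = at_d(1.5))
  expect_equal(d2, d1)
})

test_that("an all-empty patient yields empty panels without error", {
  dash <- build_dashboard(aki_cohort(), empty_alerts_df(), form,
                          as_of = at_d(0))
  expect_equal(nrow(dash$alert_history), 0L)
  expect_equal(nrow(dash$creatinine_trend), 0L)
  expect_equal(nrow(dash$meds_may_worsen_aki), 0L)
})

test_that("dashboards render to JSON and self-contained HTML", {
  labs <- rbind(mk_lab("A", 100, 0), mk_lab("A", 160, 1))
  ev <- aki_cohort(labs = labs, meds = mk_med("A", "ibuprofen", 0.5),
                   encounters = mk_enc("A"))
  alerts <- process_patient(ev, staging_config())$alerts
  dash <- build_dashboard(ev, alerts, form, as_of = at_d(2))
  js <- withr::local_tempfile(fileext = ".json")
  dashboard_json(dash, js)
  parsed <- jsonlite::fromJSON(js)
  expect_equal(parsed$patient_id, "A")
  expect_equal(nrow(parsed$alert_history), 1L)
  html <- withr::local_tempfile(fileext = ".html")
  dashboard_html(dash, html)
  txt <- paste(readLines(html), collapse = "")
  expect_match(txt, "AKI clinical summary")
  expect_match(txt, "ibuprofen")
})
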