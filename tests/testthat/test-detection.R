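cfg <- staging_config()

hist_df <- function(values, at_days) data.frame(
  value = values, collected_at = at_d(at_days))

test_that("baseline prefers the lowest value of the prior 7 days", {
  b <- compute_baseline(hist_df(c(90, 110), c(-3, -6)), at_d(0), cfg)
  expect_equal(b$method, "short_window")
  expect_equal(b$value, 90)
  expect_equal(b$n_contributing, 2L)
})

test_that("baseline falls back to the one-year median outside 7 days", {
  b <- compute_baseline(hist_df(c(100, 80, 90), c(-100, -200, -300)),
                        at_d(0), cfg)
  expect_equal(b$method, "long_window_median")
  expect_equal(b$value, 90)

  b2 <- compute_baseline(hist_df(c(100, 120), c(-50, -200)), at_d(0), cfg)
  expect_equal(b2$method, "long_window_median")
  expect_equal(b2$value, 110)  # even count: mean of the middle pair
})

test_that("baseline is unavailable with no prior results and windows are half-open", {
  expect_equal(compute_baseline(hist_df(numeric(), numeric()),
                                at_d(0), cfg)$method, "unavailable")
  # exactly 7 days old belongs to the long window, not the short one
  b <- compute_baseline(hist_df(95, -7), at_d(0), cfg)
  expect_equal(b$method, "long_window_median")
  # older than a year contributes nothing
  expect_equal(compute_baseline(hist_df(95, -400), at_d(0), cfg)$method,
               "unavailable")
  # the configurable most-recent variant
  cfg2 <- staging_config(baseline_short_method = "most_recent")
  b3 <- compute_baseline(hist_df(c(90, 110), c(-6, -2)), at_d(0), cfg2)
  expect_equal(b3$value, 110)
})

idx <- function(value, at_days = 0) list(value = value,
                                         collected_at = at_d(at_days),
                                         analyte = "creatinine")

test_that("staging applies ratio and absolute criteria in severity order", {
  b100 <- compute_baseline(hist_df(100, -1), at_d(0), cfg)
  expect_equal(stage_aki(idx(160), b100, NULL, cfg)$stage, 1L)
  expect_equal(stage_aki(idx(310), b100, NULL, cfg)$stage, 3L)
  expect_equal(stage_aki(idx(210), b100, NULL, cfg)$stage, 2L)
  expect_equal(stage_aki(idx(149.9), b100, NULL, cfg)$stage, 0L)

  # 48-h absolute rise catches a small ratio on a high baseline
  b195 <- compute_baseline(hist_df(c(200, 195), c(-2, -1)), at_d(0), cfg)
  a <- stage_aki(idx(230), b195, hist_df(195, -1), cfg)
  expect_equal(a$stage, 1L)
  expect_equal(a$rise_48h, 35)
  expect_lt(a$ratio, cfg$ratio_stage1)

  # absolute stage 3 without any baseline
  unav <- compute_baseline(hist_df(numeric(), numeric()), at_d(0), cfg)
  a3 <- stage_aki(idx(360), unav, NULL, cfg)
  expect_equal(a3$stage, 3L)
  expect_true(is.na(a3$ratio))

  expect_error(stage_aki(list(value = 5, collected_at = at_d(0),
                              analyte = "urea"), b100, NULL, cfg),
               "creatinine")
})

test_that("staging agrees with a brute-force threshold evaluator on a value grid", {
  baselines <- c(40, 60, 80, 100, 150, 200, 353.6 / 3, 300)
  indices <- seq(20, 720, by = 12.5)
  for (b in baselines) {
    bl <- compute_baseline(hist_df(b, -1), at_d(0), cfg)
    got <- vapply(indices, function(v)
      stage_aki(idx(v), bl, NULL, cfg)$stage, integer(1))
    want <- vapply(indices, function(v)
      oracle_stage(v, b, NA_real_, cfg), integer(1))
    expect_equal(got, want, info = sprintf("baseline %g", b))
  }
})

test_that("staging is monotone in the index value", {
  bl <- compute_baseline(hist_df(120, -1), at_d(0), cfg)
  stages <- vapply(seq(50, 700, by = 10), function(v)
    stage_aki(idx(v), bl, hist_df(120, -1), cfg)$stage, integer(1))
  expect_true(all(diff(stages) >= 0))
})

test_that("with absolute criteria disabled the stage counts crossed ratio thresholds", {
  cfg_r <- staging_config(abs_rise_48h = 1e9, abs_stage3 = 1e9)
  bl <- compute_baseline(hist_df(100, -1), at_d(0), cfg_r)
  for (v in seq(60, 420, by = 20)) {
    want <- sum(v / 100 >= c(1.5, 2, 3))
    expect_equal(stage_aki(idx(v), bl, NULL, cfg_r)$stage, want)
  }
})

test_that("the lifecycle alerts once per stage, on progression only", {
  ev <- aki_cohort(labs = rbind(mk_lab("A", 100, 0), mk_lab("A", 100, 1),
                                mk_lab("A", 160, 2), mk_lab("A", 210, 3),
                                mk_lab("A", 160, 4)))
  res <- process_patient(ev, cfg)
  expect_equal(res$alerts$stage, c(1L, 2L))
  expect_equal(res$alerts$episode_index, c(1L, 1L))
  expect_equal(res$alerts$raised_at, at_d(c(2, 3)))
  expect_true(res$state$in_episode)  # de-escalation is not recovery
})

test_that("recovery closes the episode and a re-alert opens the next", {
  ev <- aki_cohort(labs = rbind(mk_lab("A", 100, 0), mk_lab("A", 160, 1),
                                mk_lab("A", 105, 2), mk_lab("A", 170, 3)))
  res <- process_patient(ev, cfg)
  expect_equal(res$alerts$stage, c(1L, 1L))
  expect_equal(res$alerts$episode_index, c(1L, 2L))
  expect_equal(res$episodes$recovery_at[1], at_d(2))
  expect_true(is.na(res$episodes$recovery_at[2]))
  expect_true(all(diff(res$alerts$episode_index) >= 0))
})

test_that("alerts carry the active at-risk medications at alert time", {
  ev <- aki_cohort(
    labs = rbind(mk_lab("A", 100, 0), mk_lab("A", 160, 1)),
    meds = rbind(mk_med("A", "furosemide", 0.1),
                 mk_med("A", "ibuprofen", 0.2, dc_days = 0.5),
                 mk_med("A", "acetaminophen", 0.1)))
  res <- process_patient(ev, cfg)
  expect_equal(res$alerts$n_risk_meds, 1L)
  expect_equal(res$alerts$risk_med_classes, "diuretic")
  expect_equal(res$alerts$risk_meds[[1]]$drug_name, "furosemide")
})

test_that("patients with no creatinine yield empty output", {
  res <- process_patient(aki_cohort(labs = mk_lab("A", 9, 0,
                                                  analyte = "wbc")), cfg)
  expect_equal(nrow(res$alerts), 0L)
  expect_equal(nrow(res$episodes), 0L)
})

test_that("acknowledgment is idempotent, order-checked, and retains the alert", {
  ev <- aki_cohort(labs = rbind(mk_lab("A", 100, 0), mk_lab("A", 160, 1)))
  alert <- process_patient(ev, cfg)$alerts[1, ]
  ack <- acknowledge_alert(alert, at_d(1) + 7200)
  expect_equal(ack$status, "acknowledged")
  expect_equal(ack$acknowledged_at, at_d(1) + 7200)
  expect_identical(acknowledge_alert(ack, at_d(5)), ack)
  expect_error(acknowledge_alert(alert, at_d(0.5)), "precedes")
  # acknowledged alerts stay in the dashboard history
  dash <- build_dashboard(ev, ack, default_formulary(), as_of = at_d(2))
  expect_equal(nrow(dash$alert_history), 1L)
})

test_that("streaming detection equals the brute-force whole-history replay", {
  sim <- generate_cohort(sim_config(n_patients = 60, aki_incidence = 0.5,
                                    progression_probability = 0.4,
                                    measurement_noise_cv = 0.08, seed = 5))
  for (pid in cohort_patients(sim$cohort)) {
    ev <- patient_events(sim$cohort, pid)
    got <- process_patient(ev, cfg)
    want <- oracle_replay(ev$labs[ev$labs$analyte == "creatinine", ], cfg)
    expect_equal(got$alerts$stage, want$alerts$stage, info = pid)
    expect_equal(as.numeric(got$alerts$raised_at), want$alerts$raised_at,
                 info = pid)
    expect_equal(got$alerts$episode_index, want$alerts$episode_index,
                 info = pid)
    expect_equal(as.numeric(got$episodes$recovery_at),
                 want$episodes$recovery, info = pid)
  }
})

test_that("per episode, alerted stages strictly increase and stage pairs are unique", {
  sim <- generate_cohort(sim_config(n_patients = 80, aki_incidence = 0.6,
                                    progression_probability = 0.5,
                                    measurement_noise_cv = 0.1, seed = 9))
  alerts <- detect_alerts(sim$cohort, cfg)$alerts
  key <- paste(alerts$patient_id, alerts$episode_index, alerts$stage)
  expect_equal(anyDuplicated(key), 0L)
  for (k in split(alerts, paste(alerts$patient_id, alerts$episode_index)))
    expect_true(all(diff(k$stage[order(k$raised_at)]) > 0))
})

test_that("staging config validates its thresholds", {
  expect_error(staging_config(ratio_stage1 = 2.5), "1 < stage1 < stage2")
  expect_error(staging_config(abs_rise_48h = -1), "positive")
  cfg_json <- withr::local_tempfile(fileext = ".json")
  writeLines('{"ratio_stage1": 1.4, "med_warning_window_hours": 24}',
             cfg_json)
  c2 <- read_staging_config(cfg_json)
  expect_equal(c2$ratio_stage1, 1.4)
  expect_equal(c2$med_warning_window_hours, 24)
  expect_equal(c2$ratio_stage3, 3.0)
})
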