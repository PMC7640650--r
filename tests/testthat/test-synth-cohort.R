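test_that("identical seeds give byte-identical cohorts; seeds differ otherwise", {
  a <- generate_cohort(sim_config(n_patients = 15, seed = 4,
                                  include_supporting = TRUE))
  b <- generate_cohort(sim_config(n_patients = 15, seed = 4,
                                  include_supporting = TRUE))
  expect_identical(a, b)
  c2 <- generate_cohort(sim_config(n_patients = 15, seed = 5,
                                   include_supporting = TRUE))
  expect_false(identical(a$cohort$labs$value, c2$cohort$labs$value))
  # and the generator does not disturb the caller's RNG stream
  set.seed(99); x1 <- stats::runif(1)
  set.seed(99); invisible(generate_cohort(sim_config(n_patients = 3)))
  x2 <- stats::runif(1)
  expect_identical(x1, x2)
})

test_that("zero incidence is a clean negative control", {
  sim <- generate_cohort(sim_config(n_patients = 30, aki_incidence = 0,
                                    measurement_noise_cv = 0.02, seed = 2))
  expect_equal(nrow(sim$truth), 0L)
  expect_equal(nrow(detect_alerts(sim$cohort)$alerts), 0L)
})

test_that("full incidence with pure stage-1 mix and no noise is a positive control", {
  sim <- generate_cohort(sim_config(n_patients = 25, aki_incidence = 1,
                                    stage_mix = c(1, 0, 0),
                                    measurement_noise_cv = 0, seed = 2))
  expect_equal(nrow(sim$truth), 25L)
  alerts <- detect_alerts(sim$cohort)$alerts
  expect_equal(nrow(alerts), 25L)
  expect_true(all(alerts$stage == 1L))
  expect_equal(sort(unique(alerts$patient_id)),
               sort(sim$truth$patient_id))
})

test_that("noiseless planted episodes are recovered exactly, including progression", {
  sim <- generate_cohort(sim_config(n_patients = 60, aki_incidence = 0.6,
                                    progression_probability = 0.5,
                                    measurement_noise_cv = 0, seed = 6))
  det <- detect_alerts(sim$cohort)
  expect_equal(nrow(det$episodes), nrow(sim$truth))
  for (i in seq_len(nrow(sim$truth))) {
    tr <- sim$truth[i, ]
    al <- det$alerts[det$alerts$patient_id == tr$patient_id, ]
    expect_equal(paste(al$stage, collapse = ";"), tr$stages, info = tr$patient_id)
    expect_equal(al$episode_index, rep(1L, nrow(al)), info = tr$patient_id)
    ep <- det$episodes[det$episodes$patient_id == tr$patient_id, ]
    expect_equal(ep$onset_at, tr$onset_at, info = tr$patient_id)
    expect_equal(ep$recovery_at, tr$recovery_at, info = tr$patient_id)
  }
})

test_that("planted trajectories satisfy the ratio bands by construction", {
  sim <- generate_cohort(sim_config(n_patients = 50, aki_incidence = 1,
                                    measurement_noise_cv = 0, seed = 12))
  cr <- sim$cohort$labs
  for (i in seq_len(nrow(sim$truth))) {
    tr <- sim$truth[i, ]
    pl <- cr[cr$patient_id == tr$patient_id & cr$setting == "hospital", ]
    base <- min(pl$value[pl$collected_at < tr$onset_at])
    peak <- max(pl$value)
    peak_stage <- tr$peak_stage
    if (peak_stage == 1) expect_true(peak / base >= 1.5 * 1.05 - 1e-9)
    if (peak_stage == 2) expect_true(peak / base >= 2.0 * 1.05 - 1e-9)
    if (peak_stage == 3) expect_true(peak / base >= 3.0 * 1.05 - 1e-9 ||
                                       peak >= 353.6)
    if (peak_stage < 3) expect_lt(peak, 353.6)
  }
})

test_that("invalid configurations name their offending fields", {
  expect_error(sim_config(aki_incidence = 1.4), "aki_incidence")
  expect_error(sim_config(stage_mix = c(0.5, 0.5, 0.5)), "stage_mix")
  expect_error(sim_config(stay_days = -2), "stay_days")
  err <- tryCatch(sim_config(aki_incidence = 2, p_surgical = -1),
                  error = conditionMessage)
  expect_match(err, "aki_incidence")
  expect_match(err, "p_surgical")
})

test_that("planted truth serializes to JSON with its order flags", {
  sim <- generate_cohort(sim_config(n_patients = 20, aki_incidence = 0.8,
                                    p_risk_order_post_onset = 1, seed = 3))
  path <- withr::local_tempfile(fileext = ".json")
  write_truth_json(sim$truth, path)
  parsed <- jsonlite::fromJSON(path)
  expect_equal(nrow(parsed$episodes), nrow(sim$truth))
  expect_true(any(parsed$planted_orders$in_warning_window))
})
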