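# Hand-built alerting scenarios with worked expected outputs: the
# functional-testing analog. Each scenario is a tiny event stream plus the
# alerts/warnings the engine must produce; run_scenario() executes the
# full silent pipeline on it and check_scenario() compares.

FIXTURE_T0 <- as.POSIXct("2024-03-01 00:00:00", tz = "UTC")

fx_lab <- function(pid, value, at_days, setting = "hospital",
                   eid = "E1") data.frame(
  patient_id = pid, encounter_id = eid, analyte = "creatinine",
  value = value, collected_at = FIXTURE_T0 + at_days * 86400,
  setting = setting, stringsAsFactors = FALSE)

fx_med <- function(pid, drug, at_days, dc_days = NA, eid = "E1") data.frame(
  patient_id = pid, encounter_id = eid, drug_name = drug,
  ordered_at = FIXTURE_T0 + at_days * 86400,
  discontinued_at = if (is.na(dc_days)) na_time()
                    else FIXTURE_T0 + dc_days * 86400,
  stringsAsFactors = FALSE)

fx_enc <- function(pid, unit_type = "medical", eid = "E1") data.frame(
  patient_id = pid, encounter_id = eid,
  admit_time = FIXTURE_T0 - 0.5 * 86400, discharge_time = na_time(),
  unit_type = unit_type, unit_name = "fixture-unit",
  stringsAsFactors = FALSE)

scenario <- function(labs, expected, meds = NULL) {
  list(events = aki_cohort(
    labs = labs,
    meds = if (is.null(meds)) empty_meds() else meds,
    encounters = fx_enc(labs$patient_id[[1]])),
    expected = expected)
}

#' Fixture scenario suite
#'
#' A named list of hand-built alerting scenarios, each a small event
#' stream with its hand-computed expected output. The suite covers every
#' alerting behavior the engine implements: each stage via the ratio
#' criteria, stage 1 via the 48-h absolute rise, stage 3 via the absolute
#' value, baseline from the 7-day window vs the one-year median (odd and
#' even counts) vs unavailable, progression, de-escalation (no alert),
#' recovery with re-alert in a second episode, the medication warning
#' inside / at / outside the 48-h window, warnings with no open episode
#' and for non-risk drugs, stage attribution of warnings,
#' community-baseline usage, multi-class medication listing, and
#' discontinued-medication exclusion.
#'
#' @return named list of scenarios; each has `events` (an
#'   [aki_cohort()]) and `expected` (named list of expected quantities, a
#'   subset of the names [run_scenario()] reports).
#' @export
fixture_scenarios <- function() {
  s <- list()

  s$stage1_ratio <- scenario(
    rbind(fx_lab("A", 100, 0), fx_lab("A", 100, 1), fx_lab("A", 160, 2)),
    list(n_alerts = 1L, stages = 1L, episode_indices = 1L, n_warnings = 0L,
         baseline_method = "short_window", baseline_value = 100))

  s$stage2_ratio_first_met <- scenario(
    rbind(fx_lab("A", 100, 0), fx_lab("A", 210, 1)),
    list(n_alerts = 1L, stages = 2L, episode_indices = 1L, n_warnings = 0L))

  s$stage3_ratio <- scenario(
    rbind(fx_lab("A", 100, 0), fx_lab("A", 320, 1)),
    list(n_alerts = 1L, stages = 3L, episode_indices = 1L, n_warnings = 0L))

  # ratio 230/195 = 1.18 below stage 1, but the 48-h rise is 35 >= 26.5
  s$stage1_abs_rise_48h <- scenario(
    rbind(fx_lab("A", 200, 0), fx_lab("A", 195, 1), fx_lab("A", 230, 2)),
    list(n_alerts = 1L, stages = 1L, episode_indices = 1L, n_warnings = 0L,
         baseline_value = 195))

  # no baseline at all; 360 >= 353.6 stands alone
  s$stage3_absolute_value <- scenario(
    fx_lab("A", 360, 0),
    list(n_alerts = 1L, stages = 3L, episode_indices = 1L, n_warnings = 0L,
         baseline_method = "unavailable"))

  s$baseline_short_window_lowest <- scenario(
    rbind(fx_lab("A", 110, 0), fx_lab("A", 90, 3), fx_lab("A", 160, 6)),
    list(n_alerts = 1L, stages = 1L, episode_indices = 1L, n_warnings = 0L,
         baseline_method = "short_window", baseline_value = 90))

  s$baseline_year_median_odd <- scenario(
    rbind(fx_lab("A", 90, -300, "community"),
          fx_lab("A", 80, -200, "community"),
          fx_lab("A", 100, -100, "community"),
          fx_lab("A", 190, 0)),
    list(n_alerts = 1L, stages = 2L, episode_indices = 1L, n_warnings = 0L,
         baseline_method = "long_window_median", baseline_value = 90))

  s$baseline_year_median_even <- scenario(
    rbind(fx_lab("A", 120, -200, "community"),
          fx_lab("A", 100, -50, "community"),
          fx_lab("A", 170, 0)),
    list(n_alerts = 1L, stages = 1L, episode_indices = 1L, n_warnings = 0L,
         baseline_method = "long_window_median", baseline_value = 110))

  s$no_baseline_no_alert <- scenario(
    fx_lab("A", 150, 0),
    list(n_alerts = 0L, stages = integer(), episode_indices = integer(),
         n_warnings = 0L))

  s$progression_two_alerts <- scenario(
    rbind(fx_lab("A", 100, 0), fx_lab("A", 160, 1), fx_lab("A", 210, 2)),
    list(n_alerts = 2L, stages = c(1L, 2L), episode_indices = c(1L, 1L),
         n_warnings = 0L))

  # return to the stage-1 range is not a new alert and not a recovery
  s$deescalation_no_alert <- scenario(
    rbind(fx_lab("A", 100, 0), fx_lab("A", 160, 1), fx_lab("A", 210, 2),
          fx_lab("A", 160, 3)),
    list(n_alerts = 2L, stages = c(1L, 2L), episode_indices = c(1L, 1L),
         n_warnings = 0L, n_open_episodes = 1L))

  s$recovery_then_realert <- scenario(
    rbind(fx_lab("A", 100, 0), fx_lab("A", 100, 1), fx_lab("A", 160, 2),
          fx_lab("A", 105, 3), fx_lab("A", 170, 4)),
    list(n_alerts = 2L, stages = c(1L, 1L), episode_indices = c(1L, 2L),
         n_warnings = 0L, n_open_episodes = 1L))

  s$same_stage_no_realert <- scenario(
    rbind(fx_lab("A", 100, 0), fx_lab("A", 160, 1), fx_lab("A", 165, 2)),
    list(n_alerts = 1L, stages = 1L, episode_indices = 1L, n_warnings = 0L))

  aki_labs <- rbind(fx_lab("A", 100, 0), fx_lab("A", 100, 1),
                    fx_lab("A", 160, 2))  # onset at day 2
  s$warning_in_window <- scenario(
    aki_labs,
    list(n_alerts = 1L, stages = 1L, episode_indices = 1L, n_warnings = 1L,
         warning_stages = 1L, warning_classes = "nsaid"),
    meds = fx_med("A", "ibuprofen", 3))  # 24 h after onset

  s$warning_at_exactly_48h <- scenario(
    aki_labs,
    list(n_alerts = 1L, n_warnings = 1L, warning_stages = 1L,
         warning_classes = "nsaid"),
    meds = fx_med("A", "ibuprofen", 4))  # exactly onset + 48 h

  s$warning_at_49h <- scenario(
    aki_labs,
    list(n_alerts = 1L, n_warnings = 0L),
    meds = fx_med("A", "ibuprofen", 2 + 49 / 24))

  s$warning_no_episode <- scenario(
    rbind(fx_lab("A", 100, 0), fx_lab("A", 105, 1)),
    list(n_alerts = 0L, n_warnings = 0L),
    meds = fx_med("A", "ibuprofen", 1))

  s$warning_non_risk_drug <- scenario(
    rbind(fx_lab("A", 100, 0), fx_lab("A", 160, 1)),
    list(n_alerts = 1L, n_warnings = 0L),
    meds = fx_med("A", "acetaminophen", 1.5))

  # stage at warning time is the highest stage alerted so far (2)
  s$warning_stage_attribution <- scenario(
    rbind(fx_lab("A", 100, 0), fx_lab("A", 160, 1), fx_lab("A", 210, 1.5)),
    list(n_alerts = 2L, stages = c(1L, 2L), n_warnings = 1L,
         warning_stages = 2L, warning_classes = "diuretic"),
    meds = fx_med("A", "furosemide", 2))

  s$community_never_index <- scenario(
    rbind(fx_lab("A", 80, -100, "community"), fx_lab("A", 130, 0),
          fx_lab("A", 300, 1, "community")),
    list(n_alerts = 1L, stages = 1L, episode_indices = 1L, n_warnings = 0L,
         baseline_method = "long_window_median", baseline_value = 80))

  s$multi_class_med_listing <- scenario(
    rbind(fx_lab("A", 100, 0), fx_lab("A", 160, 1)),
    list(n_alerts = 1L, stages = 1L, n_warnings = 0L,
         first_alert_n_risk_meds = 2L,
         first_alert_risk_classes = "diuretic;nsaid"),
    meds = rbind(fx_med("A", "furosemide", 0.2),
                 fx_med("A", "ibuprofen", 0.3)))

  s$discontinued_med_not_listed <- scenario(
    rbind(fx_lab("A", 100, 0), fx_lab("A", 160, 1)),
    list(n_alerts = 1L, stages = 1L, n_warnings = 0L,
         first_alert_n_risk_meds = 0L),
    meds = fx_med("A", "furosemide", 0.1, dc_days = 0.5))

  s
}

#' Run one fixture scenario through the silent pipeline
#'
#' @param sc one element of [fixture_scenarios()].
#' @param config a [staging_config()].
#' @param formulary an `aki_formulary`.
#' @return named list of observed quantities (`n_alerts`, `stages`,
#'   `episode_indices`, `n_warnings`, `warning_stages`, `warning_classes`,
#'   `baseline_method`, `baseline_value`, `first_alert_n_risk_meds`,
#'   `first_alert_risk_classes`, `n_open_episodes`).
#' @export
run_scenario <- function(sc, config = staging_config(),
                         formulary = default_formulary()) {
  res <- run_silent(sc$events, config, formulary)
  a <- res$alerts; w <- res$warnings; e <- res$episodes
  list(
    n_alerts = nrow(a),
    stages = as.integer(a$stage),
    episode_indices = as.integer(a$episode_index),
    n_warnings = nrow(w),
    warning_stages = as.integer(w$aki_stage_at_order),
    warning_classes = w$drug_class,
    baseline_method = if (nrow(a)) a$baseline_method[[1]] else NA_character_,
    baseline_value = if (nrow(a)) a$baseline_value[[1]] else NA_real_,
    first_alert_n_risk_meds = if (nrow(a)) a$n_risk_meds[[1]] else NA_integer_,
    first_alert_risk_classes = if (nrow(a)) a$risk_med_classes[[1]]
                               else NA_character_,
    n_open_episodes = sum(is.na(e$recovery_at)))
}

#' Check a fixture scenario against its expected output
#'
#' @inheritParams run_scenario
#' @return `TRUE` when every expected quantity matches; otherwise a
#'   character vector describing the mismatches.
#' @export
check_scenario <- function(sc, config = staging_config(),
                           formulary = default_formulary()) {
  obs <- run_scenario(sc, config, formulary)
  bad <- character()
  for (nm in names(sc$expected)) {
    want <- sc$expected[[nm]]
    got <- obs[[nm]]
    same <- isTRUE(all.equal(unname(want), unname(got),
                             tolerance = 1e-9)) ||
      (length(want) == length(got) && all(want == got))
    if (!same)
      bad[[length(bad) + 1L]] <- sprintf(
        "%s: expected [%s], got [%s]", nm, paste(want, collapse = ","),
        paste(got, collapse = ","))
  }
  if (length(bad)) bad else TRUE
}
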