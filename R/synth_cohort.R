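# Seeded synthetic-cohort generator. Creatinine trajectories are
# piecewise: flat around a personal baseline, stepped up into the planted
# stage's ratio band at onset, then decayed back at recovery, with
# multiplicative lognormal measurement noise. Planted episodes satisfy the
# staging ratio criteria with a 5% margin inside the band edges, so under
# low noise the detection engine recovers them by construction.

#' Simulation configuration for synthetic cohorts
#'
#' Defaults emulate a general medical/surgical inpatient population of the
#' kind audited during a multi-unit 30-day silent alerting phase: admission
#' times staggered over a 30-day window, creatinine drawn roughly daily,
#' personal baselines lognormal around 80 umol/L, an AKI episode planted
#' in a minority of encounters with the planted stage mix matching the
#' audited alert-stage proportions, and per-class at-risk medication
#' exposure tuned so a little under half of alerts carry an active at-risk
#' medication.
#'
#' @param n_patients number of patients (one encounter each).
#' @param observation_days admissions are staggered uniformly over this
#'   many days.
#' @param stay_days length-2 range of stay length in days.
#' @param lab_interval_hours length-2 range; each patient's creatinine
#'   sampling interval is drawn uniformly from it.
#' @param baseline_meanlog,baseline_sdlog lognormal parameters of the
#'   personal baseline creatinine (umol/L).
#' @param aki_incidence probability an encounter has a planted AKI
#'   episode.
#' @param stage_mix length-3 probability vector over planted stages 1-3;
#'   must sum to 1.
#' @param progression_probability probability a planted episode (stage
#'   < 3) later progresses one further stage before recovery.
#' @param recovery_probability_per_day daily probability the elevated
#'   phase ends; the elevated duration is geometric, capped at 5 days so
#'   the 7-day baseline window always retains a pre-onset value.
#' @param risk_med_exposure named per-class probabilities of an active
#'   at-risk order spanning the stay (names diuretic, antibiotic,
#'   acei_arb, nsaid).
#' @param p_risk_order_post_onset probability an AKI encounter receives an
#'   additional at-risk order 0-72 h after onset (exercises the warning
#'   window).
#' @param measurement_noise_cv coefficient of variation of the
#'   multiplicative lognormal measurement noise (0 = noiseless).
#' @param p_surgical probability the encounter is on a surgical (vs
#'   medical) unit.
#' @param p_community_baseline probability of a pre-admission community
#'   creatinine record.
#' @param include_supporting also generate fluid and vital-sign records
#'   (dashboard fodder; off for large detection-only runs).
#' @param seed integer RNG seed; identical seeds give identical cohorts.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_patients = 450L, observation_days = 30L,
                       stay_days = c(4, 14), lab_interval_hours = c(18, 30),
                       baseline_meanlog = log(80), baseline_sdlog = 0.25,
                       aki_incidence = 0.18,
                       stage_mix = c(0.667, 0.173, 0.160),
                       progression_probability = 0,
                       recovery_probability_per_day = 0.5,
                       risk_med_exposure = c(diuretic = 0.20,
                                             antibiotic = 0.10,
                                             acei_arb = 0.12,
                                             nsaid = 0.08),
                       p_risk_order_post_onset = 0.25,
                       measurement_noise_cv = 0.02,
                       p_surgical = 0.2,
                       p_community_baseline = 0.3,
                       include_supporting = FALSE,
                       seed = 1L) {
  cfg <- as.list(environment())
  errs <- character()
  chk <- function(ok, msg) if (!ok) errs[[length(errs) + 1L]] <<- msg
  chk(is.numeric(cfg$n_patients) && cfg$n_patients >= 0, "n_patients")
  chk(length(cfg$stay_days) == 2L && all(cfg$stay_days > 0) &&
        diff(cfg$stay_days) >= 0, "stay_days")
  chk(length(cfg$lab_interval_hours) == 2L &&
        all(cfg$lab_interval_hours > 0), "lab_interval_hours")
  probs <- c(aki_incidence = cfg$aki_incidence,
             progression_probability = cfg$progression_probability,
             recovery_probability_per_day = cfg$recovery_probability_per_day,
             p_surgical = cfg$p_surgical,
             p_community_baseline = cfg$p_community_baseline,
             p_risk_order_post_onset = cfg$p_risk_order_post_onset)
  for (nm in names(probs))
    chk(is.numeric(probs[[nm]]) && probs[[nm]] >= 0 && probs[[nm]] <= 1, nm)
  chk(length(cfg$stage_mix) == 3L && all(cfg$stage_mix >= 0) &&
        abs(sum(cfg$stage_mix) - 1) < 1e-8, "stage_mix")
  chk(all(names(cfg$risk_med_exposure) %in% RISK_CLASSES) &&
        all(cfg$risk_med_exposure >= 0 & cfg$risk_med_exposure <= 1),
      "risk_med_exposure")
  chk(is.numeric(cfg$measurement_noise_cv) && cfg$measurement_noise_cv >= 0,
      "measurement_noise_cv")
  if (length(errs))
    stop("invalid simulation config field(s): ",
         paste(errs, collapse = ", "), call. = FALSE)
  structure(cfg, class = "sim_config")
}

# representative agents used by the generator, keyed by risk class
SIM_AGENTS <- list(
  diuretic = c("furosemide", "hydrochlorothiazide", "spironolactone"),
  antibiotic = c("vancomycin", "gentamicin", "tobramycin"),
  acei_arb = c("ramipril", "lisinopril", "losartan"),
  nsaid = c("ibuprofen", "naproxen", "ketorolac"))

# ratio bands per stage with a 5% margin inside the KDIGO band edges
stage_ratio_band <- function(stage, cfg = staging_config()) {
  switch(stage,
         `1` = c(cfg$ratio_stage1 * 1.05, cfg$ratio_stage2 * 0.95),
         `2` = c(cfg$ratio_stage2 * 1.05, cfg$ratio_stage3 * 0.95),
         `3` = c(cfg$ratio_stage3 * 1.05, cfg$ratio_stage3 * 1.25))
}

#' Generate a synthetic cohort with planted ground truth
#'
#' @param config a [sim_config()].
#' @param staging a [staging_config()]; the planted ratio bands are taken
#'   from its thresholds so episodes satisfy the criteria by construction.
#' @return list with `cohort` (an [aki_cohort()]) and `truth`, a data
#'   frame of planted episodes (`patient_id`, `episode_index`, `onset_at`,
#'   `stages` — semicolon-joined planted alert stages, `peak_stage`,
#'   `recovery_at`) plus attribute `planted_orders` (at-risk orders with
#'   their in/out-of-warning-window flag).
#' @export
generate_cohort <- function(config = sim_config(),
                            staging = staging_config()) {
  stopifnot(inherits(config, "sim_config"))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
  })
  set.seed(config$seed)

  t0 <- as.POSIXct("2024-03-01 00:00:00", tz = "UTC")
  labs <- list(); meds <- list(); fluids <- list(); vitals <- list()
  encounters <- list(); truth <- list(); planted_orders <- list()

  for (i in seq_len(config$n_patients)) {
    pid <- sprintf("P%04d", i)
    eid <- sprintf("E%04d", i)
    unit_type <- if (stats::runif(1) < config$p_surgical) "surgical"
                 else "medical"
    unit_name <- paste0(substr(unit_type, 1, 1), "-unit-",
                        1 + (i %% 7))
    admit <- snap_s(t0 + stats::runif(1, 0, config$observation_days) * 86400)
    stay <- stats::runif(1, config$stay_days[1], config$stay_days[2])
    discharge <- snap_s(admit + stay * 86400)
    encounters[[i]] <- data.frame(
      patient_id = pid, encounter_id = eid, admit_time = admit,
      discharge_time = discharge, unit_type = unit_type,
      unit_name = unit_name, stringsAsFactors = FALSE)

    b <- stats::rlnorm(1, config$baseline_meanlog, config$baseline_sdlog)
    interval_h <- stats::runif(1, config$lab_interval_hours[1],
                               config$lab_interval_hours[2])
    times <- seq(from = 0, to = stay * 24, by = interval_h)
    sample_times <- snap_s(admit + times * 3600)
    n <- length(sample_times)
    mult <- rep(1, n)

    has_aki <- stats::runif(1) < config$aki_incidence && n >= 4L
    onset_at <- recovery_at <- na_time()
    stages <- integer()
    if (has_aki) {
      stage <- sample.int(3L, 1L, prob = config$stage_mix)
      onset_idx <- sample(2:(n - 1L), 1L)
      dur_days <- min(1L + stats::rgeom(1, config$recovery_probability_per_day),
                      5L)
      end_idx <- onset_idx
      while (end_idx < n &&
             as.numeric(difftime(sample_times[end_idx + 1L],
                                 sample_times[onset_idx],
                                 units = "days")) <= dur_days)
        end_idx <- end_idx + 1L
      will_progress <- stage < 3L && end_idx - onset_idx >= 1L &&
        stats::runif(1) < config$progression_probability
      top_stage <- if (will_progress) stage + 1L else stage
      # cap the baseline so sub-stage-3 peaks stay below the absolute
      # stage-3 threshold (otherwise the planted stage would be wrong)
      if (top_stage < 3L) {
        band_hi <- stage_ratio_band(top_stage, staging)[2]
        b <- min(b, 0.95 * staging$abs_stage3 / (band_hi * 1.05))
      }
      band <- stage_ratio_band(stage, staging)
      r1 <- stats::runif(1, band[1], band[2])
      mult[onset_idx:end_idx] <- r1
      stages <- stage
      if (will_progress) {
        band2 <- stage_ratio_band(stage + 1L, staging)
        r2 <- stats::runif(1, band2[1], band2[2])
        mult[(onset_idx + 1L):end_idx] <- r2
        stages <- c(stage, stage + 1L)
      }
      onset_at <- sample_times[onset_idx]
      recovery_at <- if (end_idx < n) sample_times[end_idx + 1L]
                     else na_time()
      truth[[length(truth) + 1L]] <- data.frame(
        patient_id = pid, episode_index = 1L, onset_at = onset_at,
        stages = paste(stages, collapse = ";"),
        peak_stage = max(stages), recovery_at = recovery_at,
        stringsAsFactors = FALSE)
    }

    noise <- if (config$measurement_noise_cv > 0)
      stats::rlnorm(n, -config$measurement_noise_cv^2 / 2,
                    config$measurement_noise_cv) else rep(1, n)
    values <- b * mult * noise
    labs[[length(labs) + 1L]] <- data.frame(
      patient_id = pid, encounter_id = eid, analyte = "creatinine",
      value = values, collected_at = sample_times, setting = "hospital",
      stringsAsFactors = FALSE)
    if (stats::runif(1) < config$p_community_baseline) {
      labs[[length(labs) + 1L]] <- data.frame(
        patient_id = pid, encounter_id = NA_character_,
        analyte = "creatinine",
        value = b * (if (config$measurement_noise_cv > 0)
          stats::rlnorm(1, -config$measurement_noise_cv^2 / 2,
                        config$measurement_noise_cv) else 1),
        collected_at = snap_s(admit - stats::runif(1, 30, 300) * 86400),
        setting = "community", stringsAsFactors = FALSE)
    }

    for (cls in names(config$risk_med_exposure)) {
      if (stats::runif(1) < config$risk_med_exposure[[cls]]) {
        drug <- sample(SIM_AGENTS[[cls]], 1L)
        ord_at <- snap_s(admit + stats::runif(1, 0, 4) * 3600)
        meds[[length(meds) + 1L]] <- data.frame(
          patient_id = pid, encounter_id = eid, drug_name = drug,
          ordered_at = ord_at, discontinued_at = na_time(),
          stringsAsFactors = FALSE)
        planted_orders[[length(planted_orders) + 1L]] <- data.frame(
          patient_id = pid, drug_name = drug, drug_class = cls,
          ordered_at = ord_at,
          in_warning_window = has_aki && ord_at >= onset_at &&
            ord_at <= onset_at + hours(staging$med_warning_window_hours),
          stringsAsFactors = FALSE)
      }
    }
    if (has_aki && stats::runif(1) < config$p_risk_order_post_onset) {
      cls <- sample(RISK_CLASSES, 1L)
      drug <- sample(SIM_AGENTS[[cls]], 1L)
      ord_at <- snap_s(onset_at + stats::runif(1, 0, 72) * 3600)
      meds[[length(meds) + 1L]] <- data.frame(
        patient_id = pid, encounter_id = eid, drug_name = drug,
        ordered_at = ord_at, discontinued_at = na_time(),
        stringsAsFactors = FALSE)
      in_win <- ord_at <= onset_at + hours(staging$med_warning_window_hours) &&
        (is.na(recovery_at) || ord_at < recovery_at)
      planted_orders[[length(planted_orders) + 1L]] <- data.frame(
        patient_id = pid, drug_name = drug, drug_class = cls,
        ordered_at = ord_at, in_warning_window = in_win,
        stringsAsFactors = FALSE)
    }

    if (config$include_supporting) {
      shift_times <- snap_s(admit + seq(0, stay * 24, by = 8) * 3600)
      ns <- length(shift_times)
      fluids[[length(fluids) + 1L]] <- data.frame(
        patient_id = pid, encounter_id = eid,
        kind = rep(c("intake_iv", "output_urine"), each = ns),
        volume = c(stats::runif(ns, 200, 700), stats::runif(ns, 100, 500)),
        recorded_at = rep(shift_times, 2L), stringsAsFactors = FALSE)
      vitals[[length(vitals) + 1L]] <- data.frame(
        patient_id = pid, encounter_id = eid,
        kind = rep(c("heart_rate", "systolic_bp"), each = ns),
        value = c(stats::runif(ns, 60, 110), stats::runif(ns, 95, 160)),
        recorded_at = rep(shift_times, 2L), stringsAsFactors = FALSE)
    }
  }

  bind <- function(lst, empty) if (length(lst)) do.call(rbind, lst)
                               else empty
  cohort <- aki_cohort(
    labs = bind(labs, empty_labs()), meds = bind(meds, empty_meds()),
    fluids = bind(fluids, empty_fluids()),
    vitals = bind(vitals, empty_vitals()),
    encounters = bind(encounters, empty_encounters()))
  truth_df <- if (length(truth)) do.call(rbind, truth) else data.frame(
    patient_id = character(), episode_index = integer(),
    onset_at = na_time(0L), stages = character(), peak_stage = integer(),
    recovery_at = na_time(0L), stringsAsFactors = FALSE)
  rownames(truth_df) <- NULL
  attr(truth_df, "planted_orders") <-
    if (length(planted_orders)) do.call(rbind, planted_orders)
    else data.frame(patient_id = character(), drug_name = character(),
                    drug_class = character(), ordered_at = na_time(0L),
                    in_warning_window = logical(), stringsAsFactors = FALSE)
  list(cohort = cohort, truth = truth_df)
}

#' Write planted truth as JSON
#' @param truth the `truth` element of [generate_cohort()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_truth_json <- function(truth, path) {
  episodes <- truth
  episodes$onset_at <- format_ts(episodes$onset_at)
  episodes$recovery_at <- format_ts(episodes$recovery_at)
  orders <- attr(truth, "planted_orders")
  orders$ordered_at <- format_ts(orders$ordered_at)
  jsonlite::write_json(list(episodes = episodes, planted_orders = orders),
                       path, dataframe = "rows", na = "null",
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
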