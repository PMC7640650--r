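# Creatinine-based AKI detection: baseline selection (prior 7-day window,
# else one-year median), KDIGO staging of each index result, and the
# per-patient alert lifecycle (first alert, progression, recovery,
# re-alert, acknowledgment).

#' Staging configuration
#'
#' Thresholds and windows driving detection. Defaults are the KDIGO
#' guideline constants for serum creatinine (ratios 1.5 / 2.0 / 3.0 x
#' baseline; an absolute rise of 26.5 umol/L within 48 h for stage 1; an
#' absolute value of 353.6 umol/L for stage 3), with the baseline taken
#' from the prior 7 days when available and otherwise as the median of all
#' values from the preceding year.
#'
#' @param ratio_stage1,ratio_stage2,ratio_stage3 index/baseline ratio
#'   thresholds for stages 1-3. Must satisfy
#'   `1 < ratio_stage1 < ratio_stage2 < ratio_stage3`.
#' @param abs_rise_48h absolute creatinine rise (umol/L) within the prior
#'   48 h that qualifies as stage 1 regardless of ratio.
#' @param abs_stage3 absolute creatinine value (umol/L) that qualifies as
#'   stage 3 regardless of ratio.
#' @param baseline_short_window_days recent window (days) whose lowest
#'   value is the preferred baseline.
#' @param baseline_long_window_days fallback look-back (days); the baseline
#'   is the median of all values older than the short window but within
#'   this one.
#' @param med_warning_window_hours post-onset window (hours) during which a
#'   nephrotoxic order triggers an interruptive warning.
#' @param baseline_short_method `"lowest"` (default, NHS-England-style) or
#'   `"most_recent"` value within the short window.
#' @param warn_any_time_in_episode if `TRUE`, medication warnings fire for
#'   risk orders at any time during an open episode, not only within
#'   `med_warning_window_hours` of onset.
#' @return an object of class `staging_config`.
#' @export
staging_config <- function(ratio_stage1 = 1.5, ratio_stage2 = 2.0,
                           ratio_stage3 = 3.0, abs_rise_48h = 26.5,
                           abs_stage3 = 353.6,
                           baseline_short_window_days = 7L,
                           baseline_long_window_days = 365L,
                           med_warning_window_hours = 48L,
                           baseline_short_method = c("lowest", "most_recent"),
                           warn_any_time_in_episode = FALSE) {
  baseline_short_method <- match.arg(baseline_short_method)
  cfg <- list(ratio_stage1 = ratio_stage1, ratio_stage2 = ratio_stage2,
              ratio_stage3 = ratio_stage3, abs_rise_48h = abs_rise_48h,
              abs_stage3 = abs_stage3,
              baseline_short_window_days = baseline_short_window_days,
              baseline_long_window_days = baseline_long_window_days,
              med_warning_window_hours = med_warning_window_hours,
              baseline_short_method = baseline_short_method,
              warn_any_time_in_episode = isTRUE(warn_any_time_in_episode))
  if (!(1 < cfg$ratio_stage1 && cfg$ratio_stage1 < cfg$ratio_stage2 &&
        cfg$ratio_stage2 < cfg$ratio_stage3))
    stop("ratio thresholds must satisfy 1 < stage1 < stage2 < stage3",
         call. = FALSE)
  num_pos <- c("abs_rise_48h", "abs_stage3", "baseline_short_window_days",
               "baseline_long_window_days", "med_warning_window_hours")
  for (nm in num_pos)
    if (!is.numeric(cfg[[nm]]) || length(cfg[[nm]]) != 1L || cfg[[nm]] <= 0)
      stop(nm, " must be a positive scalar", call. = FALSE)
  if (cfg$baseline_long_window_days <= cfg$baseline_short_window_days)
    stop("long baseline window must exceed the short window", call. = FALSE)
  structure(cfg, class = "staging_config")
}

#' Read a staging configuration from JSON
#' @param path JSON file with any subset of [staging_config()] fields;
#'   missing fields take the defaults.
#' @return a `staging_config`.
#' @export
read_staging_config <- function(path) {
  vals <- jsonlite::fromJSON(path)
  known <- names(formals(staging_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop("unknown staging config field(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  do.call(staging_config, vals)
}

#' @export
print.staging_config <- function(x, ...) {
  cat("<staging_config>\n")
  cat(sprintf("  ratio thresholds : %.3g / %.3g / %.3g x baseline\n",
              x$ratio_stage1, x$ratio_stage2, x$ratio_stage3))
  cat(sprintf("  48-h rise        : %.4g umol/L\n", x$abs_rise_48h))
  cat(sprintf("  absolute stage 3 : %.4g umol/L\n", x$abs_stage3))
  cat(sprintf("  baseline windows : %d d (%s), else %d d median\n",
              x$baseline_short_window_days, x$baseline_short_method,
              x$baseline_long_window_days))
  cat(sprintf("  med warning      : %d h after onset\n",
              x$med_warning_window_hours))
  invisible(x)
}

#' Select the baseline creatinine for an index time
#'
#' Implements the two-tier rule: if any prior result falls inside the open
#' window `(index_time - 7 d, index_time)`, the baseline is the lowest such
#' value (`short_window`); otherwise, if any result falls in
#' `(index_time - 365 d, index_time - 7 d]`, the baseline is their median
#' (`long_window_median`, mean of the middle pair for even counts);
#' otherwise the baseline is `unavailable`. The index result itself must
#' not be in `history`.
#'
#' @param history data frame of prior creatinine results (`value`,
#'   `collected_at`), all strictly before `index_time`; community and
#'   hospital results are both eligible.
#' @param index_time POSIXct time of the index result.
#' @param config a [staging_config()].
#' @return an object of class `baseline_result`: list with `method`
#'   (`short_window`, `long_window_median`, `unavailable`), `value`,
#'   `window_start`, `window_end`, `n_contributing`.
#' @export
compute_baseline <- function(history, index_time, config = staging_config()) {
  short_start <- index_time - days(config$baseline_short_window_days)
  long_start <- index_time - days(config$baseline_long_window_days)
  t <- history$collected_at
  v <- history$value
  keep <- !is.na(t) & t < index_time
  t <- t[keep]; v <- v[keep]

  in_short <- t > short_start
  if (any(in_short)) {
    vs <- v[in_short]
    val <- if (config$baseline_short_method == "lowest") min(vs)
           else vs[which.max(as.numeric(t[in_short]))]
    return(structure(list(method = "short_window", value = val,
                          window_start = short_start,
                          window_end = index_time,
                          n_contributing = sum(in_short)),
                     class = "baseline_result"))
  }
  in_long <- t > long_start & t <= short_start
  if (any(in_long)) {
    return(structure(list(method = "long_window_median",
                          value = stats::median(v[in_long]),
                          window_start = long_start,
                          window_end = short_start,
                          n_contributing = sum(in_long)),
                     class = "baseline_result"))
  }
  structure(list(method = "unavailable", value = NA_real_,
                 window_start = long_start, window_end = index_time,
                 n_contributing = 0L),
            class = "baseline_result")
}

#' @export
print.baseline_result <- function(x, ...) {
  if (x$method == "unavailable") cat("<baseline> unavailable\n")
  else cat(sprintf("<baseline> %.4g umol/L (%s, n=%d)\n", x$value, x$method,
                   x$n_contributing))
  invisible(x)
}

#' Stage one creatinine result against its baseline
#'
#' Applies the creatinine criteria in severity order: stage 3 when the
#' ratio meets `ratio_stage3` or the absolute value meets `abs_stage3`;
#' else stage 2 on `ratio_stage2`; else stage 1 on `ratio_stage1` or a rise
#' of at least `abs_rise_48h` above the lowest result of the preceding
#' 48 h; else stage 0. Ratio criteria are skipped (not failed) when the
#' baseline is unavailable; the absolute criteria are always evaluated.
#'
#' @param index a single creatinine result: list or one-row data frame with
#'   `value`, `collected_at`, and optionally `analyte` (must be
#'   `"creatinine"` when present).
#' @param baseline a [compute_baseline()] result.
#' @param recent_48h data frame of creatinine results in
#'   `(collected_at - 48 h, collected_at)`, columns `value`,
#'   `collected_at`; may be empty.
#' @param config a [staging_config()].
#' @return an `aki_assessment`: list with `index_value`, `index_time`,
#'   `baseline`, `ratio` (NA when baseline unavailable), `rise_48h` (NA
#'   when no results in the window), `stage` in 0:3.
#' @export
stage_aki <- function(index, baseline, recent_48h = NULL,
                      config = staging_config()) {
  if (!is.null(index$analyte) && index$analyte[[1]] != "creatinine")
    stop("stage_aki expects a creatinine result, got analyte '",
         index$analyte[[1]], "'", call. = FALSE)
  value <- as.numeric(index$value[[1]])
  at <- index$collected_at[[1]]
  ratio <- if (baseline$method == "unavailable") NA_real_
           else value / baseline$value
  rise <- NA_real_
  if (!is.null(recent_48h) && nrow(recent_48h) > 0L)
    rise <- value - min(recent_48h$value)

  stage <- 0L
  if ((!is.na(ratio) && ratio >= config$ratio_stage3) ||
      value >= config$abs_stage3) {
    stage <- 3L
  } else if (!is.na(ratio) && ratio >= config$ratio_stage2) {
    stage <- 2L
  } else if ((!is.na(ratio) && ratio >= config$ratio_stage1) ||
             (!is.na(rise) && rise >= config$abs_rise_48h)) {
    stage <- 1L
  }
  structure(list(index_value = value, index_time = at, baseline = baseline,
                 ratio = ratio, rise_48h = rise, stage = stage),
            class = "aki_assessment")
}

#' @export
print.aki_assessment <- function(x, ...) {
  cat(sprintf("<aki_assessment> stage %d: index %.4g umol/L, ratio %s, 48-h rise %s\n",
              x$stage, x$index_value,
              if (is.na(x$ratio)) "n/a" else sprintf("%.3g", x$ratio),
              if (is.na(x$rise_48h)) "n/a" else sprintf("%.3g umol/L",
                                                        x$rise_48h)))
  invisible(x)
}

empty_alerts <- function() data.frame(
  alert_id = character(), patient_id = character(),
  encounter_id = character(), stage = integer(), raised_at = na_time(0L),
  episode_index = integer(), index_value = numeric(),
  baseline_value = numeric(), baseline_method = character(),
  ratio = numeric(), rise_48h = numeric(), n_risk_meds = integer(),
  risk_med_classes = character(), status = character(),
  acknowledged_at = na_time(0L), unit_type = character(),
  stringsAsFactors = FALSE)

empty_episodes <- function() data.frame(
  patient_id = character(), episode_index = integer(),
  onset_at = na_time(0L), recovery_at = na_time(0L),
  max_alerted_stage = integer(), stringsAsFactors = FALSE)

#' Run the alert lifecycle over one patient's events
#'
#' Evaluates every hospital creatinine result in arrival order, recomputing
#' the baseline from all prior results (hospital and community) each time.
#' An alert is raised at the first result assessed at stage >= 1 of an
#' episode; further alerts are raised only on progression to a stage above
#' the highest already alerted in that episode. A result assessed at
#' stage 0 closes the episode (recovery); a later qualifying result opens a
#' new episode and alerts again. De-escalation within an episode emits
#' nothing. Each alert carries the patient's active may-cause-AKI
#' medications at the alert time.
#'
#' @param events one patient's events: an `aki_cohort` (as from
#'   [patient_events()]) or a list with at least `$labs`; `$meds` and
#'   `$encounters` are used when present.
#' @param config a [staging_config()].
#' @param formulary an [aki_formulary] used to flag at-risk medications;
#'   defaults to the packaged formulary.
#' @return list with `alerts` (one row per alert, with list column
#'   `risk_meds`), `episodes` (one row per episode with onset, recovery,
#'   max alerted stage), and `state` (final `EpisodeState`: `in_episode`,
#'   `episode_index`, `onset_at`, `max_alerted_stage`).
#' @export
process_patient <- function(events, config = staging_config(),
                            formulary = default_formulary()) {
  labs <- events$labs
  meds <- if (!is.null(events$meds)) events$meds else empty_meds()
  encounters <- if (!is.null(events$encounters)) events$encounters
                else empty_encounters()
  cr <- labs[labs$analyte == "creatinine", , drop = FALSE]
  patient_id <- if (nrow(cr)) cr$patient_id[[1]] else NA_character_

  state <- list(in_episode = FALSE, episode_index = 0L,
                onset_at = na_time(), max_alerted_stage = 0L)
  alerts <- list()
  episodes <- list()
  risk_meds_col <- list()

  idx <- which(cr$setting == "hospital")
  for (i in idx) {
    t <- cr$collected_at[[i]]
    prior <- cr[seq_len(nrow(cr)) < i & cr$collected_at < t, , drop = FALSE]
    baseline <- compute_baseline(prior, t, config)
    recent <- prior[prior$collected_at > t - hours(48), , drop = FALSE]
    assess <- stage_aki(cr[i, , drop = FALSE], baseline, recent, config)

    if (assess$stage >= 1L) {
      if (!state$in_episode) {
        state$in_episode <- TRUE
        state$episode_index <- state$episode_index + 1L
        state$onset_at <- t
        state$max_alerted_stage <- 0L
      }
      if (assess$stage > state$max_alerted_stage) {
        state$max_alerted_stage <- assess$stage
        active <- active_risk_medications(meds, t, formulary)
        classes <- unique(vapply(active$drug_name, function(d)
          classify_medication(d, formulary)$drug_class, character(1)))
        enc_id <- cr$encounter_id[[i]]
        unit <- encounter_unit_type(encounters, enc_id, t)
        alerts[[length(alerts) + 1L]] <- data.frame(
          alert_id = sprintf("%s-e%d-s%d", patient_id, state$episode_index,
                             assess$stage),
          patient_id = patient_id, encounter_id = enc_id,
          stage = assess$stage, raised_at = t,
          episode_index = state$episode_index,
          index_value = assess$index_value,
          baseline_value = assess$baseline$value,
          baseline_method = assess$baseline$method,
          ratio = assess$ratio, rise_48h = assess$rise_48h,
          n_risk_meds = nrow(active),
          risk_med_classes = paste(sort(classes), collapse = ";"),
          status = "active", acknowledged_at = na_time(),
          unit_type = unit, stringsAsFactors = FALSE)
        risk_meds_col[[length(risk_meds_col) + 1L]] <- active
      }
    } else if (state$in_episode) {
      episodes[[length(episodes) + 1L]] <- data.frame(
        patient_id = patient_id, episode_index = state$episode_index,
        onset_at = state$onset_at, recovery_at = t,
        max_alerted_stage = state$max_alerted_stage,
        stringsAsFactors = FALSE)
      state$in_episode <- FALSE
      state$max_alerted_stage <- 0L
      state$onset_at <- na_time()
    }
  }
  if (state$in_episode) {
    episodes[[length(episodes) + 1L]] <- data.frame(
      patient_id = patient_id, episode_index = state$episode_index,
      onset_at = state$onset_at, recovery_at = na_time(),
      max_alerted_stage = state$max_alerted_stage, stringsAsFactors = FALSE)
  }
  alerts_df <- if (length(alerts)) do.call(rbind, alerts) else empty_alerts()
  rownames(alerts_df) <- NULL
  alerts_df$risk_meds <- risk_meds_col
  episodes_df <- if (length(episodes)) do.call(rbind, episodes)
                 else empty_episodes()
  rownames(episodes_df) <- NULL
  list(alerts = alerts_df, episodes = episodes_df, state = state)
}

# unit_type of the encounter matching enc_id, else the encounter covering t
encounter_unit_type <- function(encounters, enc_id, t) {
  if (nrow(encounters) == 0L) return(NA_character_)
  if (!is.na(enc_id)) {
    hit <- encounters[encounters$encounter_id == enc_id, , drop = FALSE]
    if (nrow(hit)) return(hit$unit_type[[1]])
  }
  cover <- encounters[!is.na(encounters$admit_time) &
                        encounters$admit_time <= t &
                        (is.na(encounters$discharge_time) |
                           t <= encounters$discharge_time), , drop = FALSE]
  if (nrow(cover)) cover$unit_type[[nrow(cover)]] else NA_character_
}

#' Detect alerts across a whole cohort
#'
#' Applies [process_patient()] to every patient.
#'
#' @param cohort an [aki_cohort()].
#' @inheritParams process_patient
#' @return list with `alerts` and `episodes` data frames pooled over
#'   patients (ordered by patient then time).
#' @export
detect_alerts <- function(cohort, config = staging_config(),
                          formulary = default_formulary()) {
  out_a <- list(); out_e <- list()
  for (pid in cohort_patients(cohort)) {
    res <- process_patient(patient_events(cohort, pid), config, formulary)
    out_a[[pid]] <- res$alerts
    out_e[[pid]] <- res$episodes
  }
  alerts <- if (length(out_a)) do.call(rbind, out_a) else empty_alerts()
  if (is.null(alerts$risk_meds)) alerts$risk_meds <- list()
  episodes <- if (length(out_e)) do.call(rbind, out_e) else empty_episodes()
  rownames(alerts) <- rownames(episodes) <- NULL
  list(alerts = alerts, episodes = episodes)
}

#' Acknowledge an alert
#'
#' Marks an active alert acknowledged at `at`. Acknowledging an already
#' acknowledged alert is an idempotent no-op. Alerts are never removed from
#' history; acknowledgment only changes their display status.
#'
#' @param alert a one-row alert data frame, as produced by
#'   [process_patient()].
#' @param at POSIXct acknowledgment time, `>= raised_at`.
#' @return the alert with `status = "acknowledged"` and `acknowledged_at`
#'   set.
#' @export
acknowledge_alert <- function(alert, at) {
  stopifnot(is.data.frame(alert), nrow(alert) == 1L)
  if (alert$status == "acknowledged") return(alert)
  if (at < alert$raised_at)
    stop("acknowledgment time precedes raised_at", call. = FALSE)
  alert$status <- "acknowledged"
  alert$acknowledged_at <- at
  alert
}

#' Write alerts as JSON-lines
#' @param alerts alerts data frame from [detect_alerts()].
#' @param path output file; one JSON object per alert.
#' @return `path`, invisibly.
#' @export
write_alerts_jsonl <- function(alerts, path) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  for (i in seq_len(nrow(alerts))) {
    rec <- as.list(alerts[i, setdiff(names(alerts), "risk_meds"),
                          drop = FALSE])
    rec$raised_at <- format_ts(alerts$raised_at[[i]])
    rec$acknowledged_at <- format_ts(alerts$acknowledged_at[[i]])
    rm <- alerts$risk_meds[[i]]
    rec$active_risk_medications <- if (!is.null(rm) && nrow(rm))
      lapply(seq_len(nrow(rm)), function(j)
        list(drug_name = rm$drug_name[[j]],
             ordered_at = format_ts(rm$ordered_at[[j]])))
      else list()
    rec <- rec[!vapply(rec, function(x) length(x) == 1L &&
                         !is.list(x) && is.na(x), logical(1))]
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, null = "null",
                                digits = NA), con)
  }
  invisible(path)
}
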