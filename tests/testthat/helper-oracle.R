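# Independent brute-force oracles, written as plain loops over the whole
# history so they share no code path with the streaming engine.

oracle_stage <- function(value, base, min48, cfg) {
  ratio <- if (is.na(base)) NA_real_ else value / base
  if (!is.na(ratio) && ratio >= cfg$ratio_stage3) return(3L)
  if (value >= cfg$abs_stage3) return(3L)
  if (!is.na(ratio) && ratio >= cfg$ratio_stage2) return(2L)
  if (!is.na(ratio) && ratio >= cfg$ratio_stage1) return(1L)
  if (!is.na(min48) && (value - min48) >= cfg$abs_rise_48h) return(1L)
  0L
}

oracle_baseline <- function(vals, ts, t, cfg) {
  short <- vals[ts > t - cfg$baseline_short_window_days * 86400 & ts < t]
  if (length(short) > 0L) return(min(short))
  long <- vals[ts > t - cfg$baseline_long_window_days * 86400 &
                 ts <= t - cfg$baseline_short_window_days * 86400]
  if (length(long) > 0L) return(stats::median(long))
  NA_real_
}

# whole-history replay for one patient's creatinine results; returns
# alerts (stage, raised_at, episode_index) and episode intervals
oracle_replay <- function(cr, cfg) {
  ts <- as.numeric(cr$collected_at)
  vals <- cr$value
  hosp <- cr$setting == "hospital"
  alerts <- data.frame(stage = integer(), raised_at = numeric(),
                       episode_index = integer())
  episodes <- data.frame(episode_index = integer(), onset = numeric(),
                         recovery = numeric())
  in_epi <- FALSE; epi <- 0L; maxstage <- 0L; onset <- NA_real_
  for (i in seq_along(ts)) {
    if (!hosp[i]) next
    prior <- seq_along(ts) < i & ts < ts[i]
    base <- oracle_baseline(vals[prior], ts[prior], ts[i], cfg)
    w48 <- prior & ts > ts[i] - 48 * 3600
    min48 <- if (any(w48)) min(vals[w48]) else NA_real_
    st <- oracle_stage(vals[i], base, min48, cfg)
    if (st >= 1L) {
      if (!in_epi) {
        in_epi <- TRUE; epi <- epi + 1L; maxstage <- 0L; onset <- ts[i]
      }
      if (st > maxstage) {
        maxstage <- st
        alerts <- rbind(alerts, data.frame(stage = st, raised_at = ts[i],
                                           episode_index = epi))
      }
    } else if (in_epi) {
      episodes <- rbind(episodes, data.frame(episode_index = epi,
                                             onset = onset,
                                             recovery = ts[i]))
      in_epi <- FALSE; maxstage <- 0L; onset <- NA_real_
    }
  }
  if (in_epi)
    episodes <- rbind(episodes, data.frame(episode_index = epi,
                                           onset = onset,
                                           recovery = NA_real_))
  list(alerts = alerts, episodes = episodes)
}

# brute-force (order x episode) pair enumeration for warnings
oracle_warnings <- function(meds, episode_tbl, alert_tbl, formulary, cfg) {
  hits <- data.frame(patient_id = character(), ordered_at = numeric(),
                     drug_name = character(), stage = integer())
  for (k in seq_len(nrow(meds))) {
    pid <- meds$patient_id[[k]]
    t <- as.numeric(meds$ordered_at[[k]])
    prof <- classify_medication(meds$drug_name[[k]], formulary)
    if (!prof$may_cause_aki) next
    epis <- episode_tbl[episode_tbl$patient_id == pid, , drop = FALSE]
    for (j in seq_len(nrow(epis))) {
      onset <- as.numeric(epis$onset_at[[j]])
      recov <- as.numeric(epis$recovery_at[[j]])
      open_at_t <- t >= onset && (is.na(recov) || t < recov)
      in_window <- t <= onset + cfg$med_warning_window_hours * 3600
      if (open_at_t && in_window) {
        al <- alert_tbl[alert_tbl$patient_id == pid &
                          alert_tbl$episode_index == epis$episode_index[[j]] &
                          as.numeric(alert_tbl$raised_at) <= t, ,
                        drop = FALSE]
        hits <- rbind(hits, data.frame(
          patient_id = pid, ordered_at = t,
          drug_name = meds$drug_name[[k]],
          stage = if (nrow(al)) max(al$stage) else 0L))
      }
    }
  }
  hits
}
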