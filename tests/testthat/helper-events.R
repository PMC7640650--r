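# Shared builders for hand-made event streams.

T0 <- as.POSIXct("2024-03-01 00:00:00", tz = "UTC")

at_d <- function(days) T0 + days * 86400

mk_lab <- function(pid, value, at_days, setting = "hospital",
                   analyte = "creatinine", eid = "E1") data.frame(
  patient_id = pid, encounter_id = eid, analyte = analyte, value = value,
  collected_at = at_d(at_days), setting = setting, stringsAsFactors = FALSE)

mk_med <- function(pid, drug, at_days, dc_days = NA, eid = "E1") {
  dc <- if (is.na(dc_days)) as.POSIXct(NA, tz = "UTC") else at_d(dc_days)
  data.frame(patient_id = pid, encounter_id = eid, drug_name = drug,
             ordered_at = at_d(at_days), discontinued_at = dc,
             stringsAsFactors = FALSE)
}

mk_fluid <- function(pid, kind, volume, at_days, eid = "E1") data.frame(
  patient_id = pid, encounter_id = eid, kind = kind, volume = volume,
  recorded_at = at_d(at_days), stringsAsFactors = FALSE)

mk_enc <- function(pid, unit_type = "medical", eid = "E1",
                   admit_days = -1, discharge_days = NA) {
  dis <- if (is.na(discharge_days)) as.POSIXct(NA, tz = "UTC")
         else at_d(discharge_days)
  data.frame(patient_id = pid, encounter_id = eid,
             admit_time = at_d(admit_days), discharge_time = dis,
             unit_type = unit_type, unit_name = "u1",
             stringsAsFactors = FALSE)
}

empty_cohort_fluids <- function() aki_cohort()$fluids

empty_alerts_df <- function() process_patient(aki_cohort(),
                                              staging_config())$alerts

# canonical full ordering so cohorts can be compared as event multisets
canon <- function(df) {
  if (nrow(df) == 0L) return(df)
  key <- do.call(paste, c(lapply(df, as.character), sep = "\r"))
  out <- df[order(key), , drop = FALSE]
  rownames(out) <- NULL
  out
}

expect_cohort_equal <- function(a, b, tolerance = 1e-12) {
  for (nm in c("labs", "meds", "fluids", "vitals", "encounters"))
    expect_equal(canon(a[[nm]]), canon(b[[nm]]), tolerance = tolerance,
                 info = nm)
}
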