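# Clinical summary dashboard: a pure aggregation of one patient's events
# at a point in time — alert history, analyte trends, medication panels,
# fluid balance / urine output by interval, vitals, infection markers and
# visit history.

#' Net fluid balance over an interval
#'
#' Sum of intake volumes minus sum of output volumes for records with
#' `recorded_at` in the half-open interval `[start, end)`.
#'
#' @param fluids fluid-record data frame (`kind`, `volume`, `recorded_at`).
#' @param start,end POSIXct interval bounds.
#' @return net balance in mL (0 for an empty interval).
#' @export
fluid_balance <- function(fluids, start, end) {
  if (is.null(fluids) || nrow(fluids) == 0L) return(0)
  f <- fluids[!is.na(fluids$recorded_at) & fluids$recorded_at >= start &
                fluids$recorded_at < end, , drop = FALSE]
  if (nrow(f) == 0L) return(0)
  intake <- sum(f$volume[f$kind %in% c("intake_iv", "intake_oral")])
  output <- sum(f$volume[f$kind %in% c("output_urine", "output_other")])
  intake - output
}

#' Urine output over an interval, optionally weight-indexed
#'
#' @inheritParams fluid_balance
#' @param weight_kg optional patient weight; when given, a rate in
#'   mL/kg/h is returned alongside the total.
#' @return list with `total_ml` and `rate_ml_kg_h` (`NA` when weight is
#'   absent).
#' @export
urine_output_rate <- function(fluids, start, end, weight_kg = NULL) {
  hrs <- as.numeric(difftime(end, start, units = "hours"))
  if (!is.finite(hrs) || hrs <= 0)
    stop("interval duration must be positive", call. = FALSE)
  total <- 0
  if (!is.null(fluids) && nrow(fluids) > 0L) {
    f <- fluids[!is.na(fluids$recorded_at) & fluids$recorded_at >= start &
                  fluids$recorded_at < end & fluids$kind == "output_urine", ,
                drop = FALSE]
    total <- sum(f$volume)
  }
  rate <- NA_real_
  if (!is.null(weight_kg)) {
    if (!is.numeric(weight_kg) || weight_kg <= 0)
      stop("weight_kg must be positive", call. = FALSE)
    rate <- total / weight_kg / hrs
  }
  list(total_ml = total, rate_ml_kg_h = rate)
}

ELECTROLYTES <- c("sodium", "potassium", "bicarbonate")

trend <- function(labs, analyte, as_of) {
  t <- labs[labs$analyte == analyte & labs$collected_at <= as_of,
            c("collected_at", "value"), drop = FALSE]
  rownames(t) <- NULL
  t
}

#' Assemble the AKI clinical summary dashboard for one patient
#'
#' A pure function of the events at or before `as_of`: alert history
#' (acknowledged alerts included — alerts are permanently retained),
#' creatinine / urea / electrolyte trends, the may-worsen-AKI and
#' renally-cleared medication panels (a drug carrying both flags appears in
#' both), urine output and net fluid balance per interval, IV therapies,
#' vitals, infection markers (WBC trend, urinalysis and urine-protein
#' results) and visit history.
#'
#' @param events one patient's events ([patient_events()] or an
#'   `aki_cohort` restricted to the patient).
#' @param alerts alert data frame for the patient (from [detect_alerts()]
#'   or [process_patient()]).
#' @param formulary an `aki_formulary`.
#' @param as_of POSIXct time the dashboard is built at; later events are
#'   excluded everywhere.
#' @param interval_hours width of the fluid/urine summary bins (default 8,
#'   nursing-shift granularity).
#' @return an object of class `aki_dashboard`.
#' @export
build_dashboard <- function(events, alerts, formulary = default_formulary(),
                            as_of, interval_hours = 8) {
  labs <- events$labs[!is.na(events$labs$collected_at) &
                        events$labs$collected_at <= as_of, , drop = FALSE]
  meds <- events$meds[!is.na(events$meds$ordered_at) &
                        events$meds$ordered_at <= as_of, , drop = FALSE]
  fluids <- events$fluids[!is.na(events$fluids$recorded_at) &
                            events$fluids$recorded_at <= as_of, ,
                          drop = FALSE]
  vitals <- events$vitals[!is.na(events$vitals$recorded_at) &
                            events$vitals$recorded_at <= as_of, ,
                          drop = FALSE]
  encounters <- events$encounters[!is.na(events$encounters$admit_time) &
                                    events$encounters$admit_time <= as_of, ,
                                  drop = FALSE]
  patient_id <- unique(c(labs$patient_id, meds$patient_id,
                         fluids$patient_id, vitals$patient_id,
                         encounters$patient_id))
  patient_id <- if (length(patient_id)) patient_id[[1]] else NA_character_

  prof <- lapply(meds$drug_name, classify_medication, formulary = formulary)
  worsen <- meds[vapply(prof, `[[`, logical(1), "may_cause_aki"), ,
                 drop = FALSE]
  renal <- meds[vapply(prof, `[[`, logical(1), "renally_cleared"), ,
                drop = FALSE]

  # interval grid anchored at admission (else first fluid record)
  anchor <- if (nrow(encounters)) min(encounters$admit_time)
            else if (nrow(fluids)) min(fluids$recorded_at) else as_of
  breaks <- seq(from = anchor, to = as_of + hours(interval_hours),
                by = interval_hours * 3600)
  intervals <- data.frame(start = breaks[-length(breaks)],
                          end = breaks[-1L])
  intervals <- intervals[intervals$start <= as_of, , drop = FALSE]
  urine <- vapply(seq_len(nrow(intervals)), function(i)
    urine_output_rate(fluids, intervals$start[[i]],
                      intervals$end[[i]])$total_ml, numeric(1))
  balance <- vapply(seq_len(nrow(intervals)), function(i)
    fluid_balance(fluids, intervals$start[[i]], intervals$end[[i]]),
    numeric(1))

  al <- alerts[alerts$patient_id %in% patient_id &
                 alerts$raised_at <= as_of, , drop = FALSE]
  structure(list(
    patient_id = patient_id, as_of = as_of,
    alert_history = al,
    creatinine_trend = trend(labs, "creatinine", as_of),
    urea_trend = trend(labs, "urea", as_of),
    electrolyte_trends = stats::setNames(
      lapply(ELECTROLYTES, trend, labs = labs, as_of = as_of), ELECTROLYTES),
    meds_may_worsen_aki = worsen,
    meds_renally_cleared = renal,
    urine_output_by_interval = cbind(intervals, total_ml = urine),
    fluid_balance_by_interval = cbind(intervals, net_ml = balance),
    iv_therapies = fluids[fluids$kind == "intake_iv", , drop = FALSE],
    vitals = vitals,
    infection_markers = list(
      wbc_trend = trend(labs, "wbc", as_of),
      urinalysis = labs[labs$analyte %in% c("urinalysis", "urine_protein"), ,
                        drop = FALSE]),
    visit_history = encounters
  ), class = "aki_dashboard")
}

#' @export
print.aki_dashboard <- function(x, ...) {
  cat(sprintf("<aki_dashboard> patient %s as of %s\n", x$patient_id,
              format_ts(x$as_of)))
  cat(sprintf("  alerts: %d | creatinine points: %d | risk meds: %d | renally cleared: %d\n",
              nrow(x$alert_history), nrow(x$creatinine_trend),
              nrow(x$meds_may_worsen_aki), nrow(x$meds_renally_cleared)))
  cat(sprintf("  fluid intervals: %d | vitals: %d | visits: %d\n",
              nrow(x$fluid_balance_by_interval), nrow(x$vitals),
              nrow(x$visit_history)))
  invisible(x)
}

#' Serialize a dashboard to JSON
#' @param dashboard an `aki_dashboard`.
#' @param path optional file; when `NULL` the JSON string is returned.
#' @return JSON string (invisibly when written to `path`).
#' @export
dashboard_json <- function(dashboard, path = NULL) {
  x <- unclass(dashboard)
  x$as_of <- format_ts(x$as_of)
  if (nrow(x$alert_history)) x$alert_history$risk_meds <- NULL
  fmt_times <- function(df) {
    for (nm in names(df))
      if (inherits(df[[nm]], "POSIXct")) df[[nm]] <- format_ts(df[[nm]])
    df
  }
  x <- rapply(x, fmt_times, classes = "data.frame", how = "replace")
  js <- jsonlite::toJSON(x, auto_unbox = TRUE, null = "null", na = "null",
                         digits = NA, POSIXt = "ISO8601", pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' Render a dashboard as a single self-contained HTML page
#' @param dashboard an `aki_dashboard`.
#' @param path output HTML file.
#' @return `path`, invisibly.
#' @export
dashboard_html <- function(dashboard, path) {
  esc <- function(x) {
    x <- gsub("&", "&amp;", as.character(x), fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub(">", "&gt;", x, fixed = TRUE)
  }
  tbl <- function(df, title) {
    if (is.null(df) || nrow(df) == 0L)
      return(sprintf("<h2>%s</h2><p>none</p>", esc(title)))
    df <- df[, !vapply(df, is.list, logical(1)), drop = FALSE]
    for (nm in names(df))
      if (inherits(df[[nm]], "POSIXct")) df[[nm]] <- format_ts(df[[nm]])
    head_row <- paste0("<th>", esc(names(df)), "</th>", collapse = "")
    body <- paste(vapply(seq_len(nrow(df)), function(i)
      paste0("<tr>", paste0("<td>", esc(unlist(df[i, ])), "</td>",
                            collapse = ""), "</tr>"), character(1)),
      collapse = "\n")
    sprintf("<h2>%s</h2><table><tr>%s</tr>%s</table>", esc(title), head_row,
            body)
  }
  sections <- c(
    sprintf("<h1>AKI clinical summary &mdash; patient %s (as of %s)</h1>",
            esc(dashboard$patient_id), esc(format_ts(dashboard$as_of))),
    tbl(dashboard$alert_history, "AKI alert history"),
    tbl(dashboard$creatinine_trend, "Creatinine trend (umol/L)"),
    tbl(dashboard$urea_trend, "Urea trend"),
    tbl(do.call(rbind, Map(function(nm, df) {
      df$analyte <- rep(nm, nrow(df)); df
    }, names(dashboard$electrolyte_trends), dashboard$electrolyte_trends)),
      "Electrolytes"),
    tbl(dashboard$meds_may_worsen_aki, "Medications that may worsen AKI"),
    tbl(dashboard$meds_renally_cleared, "Renally cleared medications"),
    tbl(dashboard$urine_output_by_interval, "Urine output by interval"),
    tbl(dashboard$fluid_balance_by_interval, "Fluid balance by interval"),
    tbl(dashboard$iv_therapies, "IV therapies"),
    tbl(dashboard$vitals, "Vital signs"),
    tbl(dashboard$infection_markers$wbc_trend, "WBC trend"),
    tbl(dashboard$infection_markers$urinalysis,
        "Urinalysis / urine protein"),
    tbl(dashboard$visit_history, "Visit history"))
  html <- paste0(
    "<!DOCTYPE html><html><head><meta charset=\"utf-8\">",
    "<title>AKI clinical summary</title>",
    "<style>body{font-family:sans-serif;margin:2em}table{border-collapse:collapse}",
    "td,th{border:1px solid #999;padding:2px 8px;font-size:90%}</style>",
    "</head><body>", paste(sections, collapse = "\n"), "</body></html>")
  writeLines(html, path)
  invisible(path)
}
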