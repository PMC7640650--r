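# Patient event streams: the in-memory cohort container and the CSV /
# JSON-lines readers and writers every other component consumes.
#
# A cohort is a list of five data frames (labs, meds, fluids, vitals,
# encounters), each time-sorted with stable tie-breaking by input row order.
# On disk a cohort is a single flat stream of rows discriminated by a
# `record_kind` column: lab, medication, fluid, vital, encounter.

ANALYTES <- c("creatinine", "urea", "sodium", "potassium", "bicarbonate",
              "wbc", "urinalysis", "urine_protein", "other")
QUANT_ANALYTES <- setdiff(ANALYTES, c("urinalysis", "other"))
FLUID_KINDS <- c("intake_iv", "intake_oral", "output_urine", "output_other")
VITAL_KINDS <- c("heart_rate", "systolic_bp", "diastolic_bp")
UNIT_TYPES <- c("medical", "surgical")
LAB_SETTINGS <- c("hospital", "community")
RECORD_KINDS <- c("lab", "medication", "fluid", "vital", "encounter")

STREAM_COLS <- c("record_kind", "patient_id", "encounter_id", "timestamp",
                 "end_timestamp", "analyte", "setting", "drug_name", "kind",
                 "unit_type", "unit_name", "value")

empty_labs <- function() data.frame(
  patient_id = character(), encounter_id = character(),
  analyte = character(), value = numeric(),
  collected_at = na_time(0L), setting = character(),
  stringsAsFactors = FALSE)

empty_meds <- function() data.frame(
  patient_id = character(), encounter_id = character(),
  drug_name = character(), ordered_at = na_time(0L),
  discontinued_at = na_time(0L), stringsAsFactors = FALSE)

empty_fluids <- function() data.frame(
  patient_id = character(), encounter_id = character(),
  kind = character(), volume = numeric(), recorded_at = na_time(0L),
  stringsAsFactors = FALSE)

empty_vitals <- function() data.frame(
  patient_id = character(), encounter_id = character(),
  kind = character(), value = numeric(), recorded_at = na_time(0L),
  stringsAsFactors = FALSE)

empty_encounters <- function() data.frame(
  patient_id = character(), encounter_id = character(),
  admit_time = na_time(0L), discharge_time = na_time(0L),
  unit_type = character(), unit_name = character(),
  stringsAsFactors = FALSE)

#' Construct a patient-event cohort
#'
#' Bundles the five event tables into an `aki_cohort`. Each table is sorted
#' ascending by its primary timestamp; ties keep their input order (stable
#' sort), so replay is deterministic.
#'
#' @param labs data frame: `patient_id`, `encounter_id`, `analyte`, `value`
#'   (creatinine in umol/L), `collected_at` (POSIXct UTC), `setting`
#'   (`"hospital"` or `"community"`).
#' @param meds data frame: `patient_id`, `encounter_id`, `drug_name`,
#'   `ordered_at`, `discontinued_at` (NA while active).
#' @param fluids data frame: `patient_id`, `encounter_id`, `kind` (one of
#'   intake_iv, intake_oral, output_urine, output_other), `volume` (mL),
#'   `recorded_at`.
#' @param vitals data frame: `patient_id`, `encounter_id`, `kind`
#'   (heart_rate, systolic_bp, diastolic_bp), `value`, `recorded_at`.
#' @param encounters data frame: `patient_id`, `encounter_id`, `admit_time`,
#'   `discharge_time` (optional), `unit_type` (medical/surgical),
#'   `unit_name`.
#' @return an object of class `aki_cohort`.
#' @export
aki_cohort <- function(labs = empty_labs(), meds = empty_meds(),
                       fluids = empty_fluids(), vitals = empty_vitals(),
                       encounters = empty_encounters()) {
  sort_by <- function(df, col) {
    if (nrow(df) == 0L) return(df)
    df <- df[order(df[[col]]), , drop = FALSE]  # order() is stable
    rownames(df) <- NULL
    df
  }
  structure(list(
    labs = sort_by(as.data.frame(labs), "collected_at"),
    meds = sort_by(as.data.frame(meds), "ordered_at"),
    fluids = sort_by(as.data.frame(fluids), "recorded_at"),
    vitals = sort_by(as.data.frame(vitals), "recorded_at"),
    encounters = sort_by(as.data.frame(encounters), "admit_time")
  ), class = "aki_cohort")
}

#' @export
print.aki_cohort <- function(x, ...) {
  n_pat <- length(cohort_patients(x))
  cat(sprintf(
    "<aki_cohort> %d patient(s): %d labs, %d med orders, %d fluid, %d vital, %d encounter rows\n",
    n_pat, nrow(x$labs), nrow(x$meds), nrow(x$fluids), nrow(x$vitals),
    nrow(x$encounters)))
  invisible(x)
}

#' Patient identifiers present in a cohort
#' @param cohort an `aki_cohort`.
#' @return sorted character vector of patient ids.
#' @export
cohort_patients <- function(cohort) {
  sort(unique(c(cohort$labs$patient_id, cohort$meds$patient_id,
                cohort$fluids$patient_id, cohort$vitals$patient_id,
                cohort$encounters$patient_id)))
}

# row-level validation of a flat stream data frame; errors name row indices
validate_stream <- function(df) {
  n <- nrow(df)
  errs <- character()
  add <- function(i, msg) errs[[length(errs) + 1L]] <<- sprintf("row %d: %s", i, msg)
  kind <- as.character(df$record_kind)
  pid <- as.character(df$patient_id)
  ts <- parse_ts(df$timestamp)
  val <- suppressWarnings(as.numeric(df$value))
  for (i in seq_len(n)) {
    if (is.na(kind[i]) || !kind[i] %in% RECORD_KINDS) {
      add(i, sprintf("unknown record_kind '%s'", kind[i])); next
    }
    if (is.na(pid[i]) || !nzchar(pid[i])) add(i, "missing patient_id")
    if (is.na(ts[i])) add(i, sprintf("malformed timestamp '%s'", df$timestamp[i]))
    if (kind[i] == "lab") {
      an <- as.character(df$analyte[i])
      if (!isTRUE(an %in% ANALYTES)) add(i, sprintf("unknown analyte '%s'", an))
      else if (an %in% QUANT_ANALYTES && (is.na(val[i]) || val[i] <= 0))
        add(i, sprintf("non-positive value '%s' for quantitative analyte %s",
                       df$value[i], an))
      st <- as.character(df$setting[i])
      if (!is.na(st) && nzchar(st) && !st %in% LAB_SETTINGS)
        add(i, sprintf("unknown lab setting '%s'", st))
    } else if (kind[i] == "medication") {
      if (is.na(df$drug_name[i]) || !nzchar(as.character(df$drug_name[i])))
        add(i, "missing drug_name")
      dt <- parse_ts(df$end_timestamp[i])
      if (!is.na(dt) && !is.na(ts[i]) && dt < ts[i])
        add(i, "discontinued before ordered")
    } else if (kind[i] == "fluid") {
      if (!isTRUE(as.character(df$kind[i]) %in% FLUID_KINDS))
        add(i, sprintf("unknown fluid kind '%s'", df$kind[i]))
      if (is.na(val[i]) || val[i] < 0)
        add(i, sprintf("negative fluid volume '%s'", df$value[i]))
    } else if (kind[i] == "vital") {
      if (!isTRUE(as.character(df$kind[i]) %in% VITAL_KINDS))
        add(i, sprintf("unknown vital kind '%s'", df$kind[i]))
      if (is.na(val[i]) || val[i] <= 0)
        add(i, sprintf("non-positive vital value '%s'", df$value[i]))
    } else if (kind[i] == "encounter") {
      ut <- as.character(df$unit_type[i])
      if (!isTRUE(ut %in% UNIT_TYPES))
        add(i, sprintf("unknown unit_type '%s'", ut))
      dt <- parse_ts(df$end_timestamp[i])
      if (!is.na(dt) && !is.na(ts[i]) && dt < ts[i])
        add(i, "discharge before admission")
    }
  }
  if (length(errs) > 0L)
    stop("invalid event stream:\n  ", paste(errs, collapse = "\n  "),
         call. = FALSE)
  invisible(TRUE)
}

#' Read a patient event stream
#'
#' Reads a flat event stream (CSV with a header, or JSON-lines with one
#' object per line) into an [aki_cohort()]. Rows carry a `record_kind`
#' discriminator (`lab`, `medication`, `fluid`, `vital`, `encounter`).
#' Every row is validated; violations are reported with their row index.
#' Events are re-sorted ascending by timestamp with input order breaking
#' ties, so the result is independent of on-disk row order.
#'
#' @param path file to read.
#' @param format `"csv"` or `"jsonl"`.
#' @param creatinine_unit unit of creatinine values on disk; `"umol_l"`
#'   (default) or `"mg_dl"`, the latter converted by x 88.4 at read time.
#' @return an `aki_cohort`; an empty file yields an empty cohort.
#' @export
read_event_stream <- function(path, format = c("csv", "jsonl"),
                              creatinine_unit = c("umol_l", "mg_dl")) {
  format <- match.arg(format)
  creatinine_unit <- match.arg(creatinine_unit)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- if (format == "csv") {
    raw <- tryCatch(utils::read.csv(path, colClasses = "character",
                                    fileEncoding = "UTF-8"),
                    error = function(e) NULL)
    if (is.null(raw) || nrow(raw) == 0L) NULL else raw
  } else {
    lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines) == 0L) NULL else {
      recs <- lapply(seq_along(lines), function(i) {
        obj <- tryCatch(jsonlite::fromJSON(lines[[i]]),
                        error = function(e)
                          stop(sprintf("row %d: malformed JSON", i),
                               call. = FALSE))
        as.list(obj)
      })
      do.call(rbind, lapply(recs, function(r) {
        row <- as.list(rep(NA_character_, length(STREAM_COLS)))
        names(row) <- STREAM_COLS
        for (nm in intersect(names(r), STREAM_COLS))
          if (!is.null(r[[nm]])) row[[nm]] <- as.character(r[[nm]])
        as.data.frame(row, stringsAsFactors = FALSE)
      }))
    }
  }
  if (is.null(df)) return(aki_cohort())
  for (nm in setdiff(STREAM_COLS, names(df))) df[[nm]] <- NA_character_
  df[df == ""] <- NA
  validate_stream(df)
  stream_to_cohort(df, creatinine_unit)
}

stream_to_cohort <- function(df, creatinine_unit = "umol_l") {
  kind <- as.character(df$record_kind)
  num <- function(x) suppressWarnings(as.numeric(x))
  chr <- function(x) as.character(x)
  pick <- function(k) df[kind == k, , drop = FALSE]

  l <- pick("lab")
  labs <- data.frame(
    patient_id = chr(l$patient_id), encounter_id = chr(l$encounter_id),
    analyte = chr(l$analyte), value = num(l$value),
    collected_at = parse_ts(l$timestamp),
    setting = ifelse(is.na(chr(l$setting)), "hospital", chr(l$setting)),
    stringsAsFactors = FALSE)
  if (creatinine_unit == "mg_dl") {
    cr <- labs$analyte == "creatinine"
    labs$value[cr] <- labs$value[cr] * 88.4
  }

  m <- pick("medication")
  meds <- data.frame(
    patient_id = chr(m$patient_id), encounter_id = chr(m$encounter_id),
    drug_name = chr(m$drug_name), ordered_at = parse_ts(m$timestamp),
    discontinued_at = parse_ts(m$end_timestamp), stringsAsFactors = FALSE)

  f <- pick("fluid")
  fluids <- data.frame(
    patient_id = chr(f$patient_id), encounter_id = chr(f$encounter_id),
    kind = chr(f$kind), volume = num(f$value),
    recorded_at = parse_ts(f$timestamp), stringsAsFactors = FALSE)

  v <- pick("vital")
  vitals <- data.frame(
    patient_id = chr(v$patient_id), encounter_id = chr(v$encounter_id),
    kind = chr(v$kind), value = num(v$value),
    recorded_at = parse_ts(v$timestamp), stringsAsFactors = FALSE)

  e <- pick("encounter")
  encounters <- data.frame(
    patient_id = chr(e$patient_id), encounter_id = chr(e$encounter_id),
    admit_time = parse_ts(e$timestamp),
    discharge_time = parse_ts(e$end_timestamp),
    unit_type = chr(e$unit_type), unit_name = chr(e$unit_name),
    stringsAsFactors = FALSE)

  aki_cohort(labs, meds, fluids, vitals, encounters)
}

cohort_to_stream <- function(cohort) {
  blank <- function(n) rep(NA_character_, n)
  # %.17g guarantees an exact double round-trip through text
  num_chr <- function(x) sprintf("%.17g", x)
  rows <- list()
  l <- cohort$labs
  if (nrow(l)) rows$lab <- data.frame(
    record_kind = "lab", patient_id = l$patient_id,
    encounter_id = l$encounter_id, timestamp = format_ts(l$collected_at),
    end_timestamp = blank(nrow(l)), analyte = l$analyte,
    setting = l$setting, drug_name = blank(nrow(l)), kind = blank(nrow(l)),
    unit_type = blank(nrow(l)), unit_name = blank(nrow(l)),
    value = num_chr(l$value), stringsAsFactors = FALSE)
  m <- cohort$meds
  if (nrow(m)) rows$medication <- data.frame(
    record_kind = "medication", patient_id = m$patient_id,
    encounter_id = m$encounter_id, timestamp = format_ts(m$ordered_at),
    end_timestamp = format_ts(m$discontinued_at), analyte = blank(nrow(m)),
    setting = blank(nrow(m)), drug_name = m$drug_name, kind = blank(nrow(m)),
    unit_type = blank(nrow(m)), unit_name = blank(nrow(m)),
    value = blank(nrow(m)), stringsAsFactors = FALSE)
  f <- cohort$fluids
  if (nrow(f)) rows$fluid <- data.frame(
    record_kind = "fluid", patient_id = f$patient_id,
    encounter_id = f$encounter_id, timestamp = format_ts(f$recorded_at),
    end_timestamp = blank(nrow(f)), analyte = blank(nrow(f)),
    setting = blank(nrow(f)), drug_name = blank(nrow(f)), kind = f$kind,
    unit_type = blank(nrow(f)), unit_name = blank(nrow(f)),
    value = num_chr(f$volume), stringsAsFactors = FALSE)
  v <- cohort$vitals
  if (nrow(v)) rows$vital <- data.frame(
    record_kind = "vital", patient_id = v$patient_id,
    encounter_id = v$encounter_id, timestamp = format_ts(v$recorded_at),
    end_timestamp = blank(nrow(v)), analyte = blank(nrow(v)),
    setting = blank(nrow(v)), drug_name = blank(nrow(v)), kind = v$kind,
    unit_type = blank(nrow(v)), unit_name = blank(nrow(v)),
    value = num_chr(v$value), stringsAsFactors = FALSE)
  e <- cohort$encounters
  if (nrow(e)) rows$encounter <- data.frame(
    record_kind = "encounter", patient_id = e$patient_id,
    encounter_id = e$encounter_id, timestamp = format_ts(e$admit_time),
    end_timestamp = format_ts(e$discharge_time), analyte = blank(nrow(e)),
    setting = blank(nrow(e)), drug_name = blank(nrow(e)),
    kind = blank(nrow(e)), unit_type = e$unit_type, unit_name = e$unit_name,
    value = blank(nrow(e)), stringsAsFactors = FALSE)
  if (length(rows) == 0L) {
    out <- as.data.frame(lapply(STREAM_COLS, function(x) character()),
                         stringsAsFactors = FALSE)
    names(out) <- STREAM_COLS
    return(out)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[, STREAM_COLS]
}

#' Write a patient event stream
#'
#' Serializes a cohort to the flat on-disk stream. Round-trips with
#' [read_event_stream()]: reading a written file reproduces the cohort
#' event for event.
#'
#' @param cohort an `aki_cohort`.
#' @inheritParams read_event_stream
#' @return `path`, invisibly.
#' @export
write_event_stream <- function(cohort, path, format = c("csv", "jsonl")) {
  format <- match.arg(format)
  stopifnot(inherits(cohort, "aki_cohort"))
  df <- cohort_to_stream(cohort)
  if (format == "csv") {
    utils::write.csv(df, path, row.names = FALSE, na = "",
                     fileEncoding = "UTF-8")
  } else {
    con <- file(path, open = "w", encoding = "UTF-8")
    on.exit(close(con))
    for (i in seq_len(nrow(df))) {
      rec <- as.list(df[i, , drop = FALSE])
      rec <- rec[!vapply(rec, function(x) is.na(x[[1]]), logical(1))]
      writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, null = "null"),
                 con)
    }
  }
  invisible(path)
}

#' Restrict a cohort to one patient's events
#' @param cohort an `aki_cohort`.
#' @param patient_id the patient to keep.
#' @return an `aki_cohort` containing only that patient's events.
#' @export
patient_events <- function(cohort, patient_id) {
  sel <- function(df, col = "patient_id") df[df[[col]] == patient_id, ,
                                             drop = FALSE]
  aki_cohort(sel(cohort$labs), sel(cohort$meds), sel(cohort$fluids),
             sel(cohort$vitals), sel(cohort$encounters))
}
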