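# Formulary-driven identification of AKI-risk medications and the
# interruptive adverse-medication warning raised at order entry within the
# post-onset window.

RISK_CLASSES <- c("diuretic", "antibiotic", "acei_arb", "nsaid")

normalize_drug <- function(x) tolower(trimws(as.character(x)))

#' Load a medication formulary
#'
#' A formulary maps normalized drug names to a risk class (`diuretic`,
#' `antibiotic`, `acei_arb`, `nsaid`, or `other`) and two flags:
#' `may_cause_aki` (drives stage-alert medication lists and order-entry
#' warnings) and `renally_cleared` (drives the dashboard accumulation-risk
#' panel). Lookup is total: names not in the formulary resolve to class
#' `other` with both flags false.
#'
#' @param path JSON file: an object mapping drug name to
#'   `{risk_class, may_cause_aki, renally_cleared}`.
#' @return an object of class `aki_formulary` (data frame with columns
#'   `name`, `risk_class`, `may_cause_aki`, `renally_cleared`).
#' @export
read_formulary <- function(path) {
  raw <- jsonlite::fromJSON(path)
  if (length(raw) == 0L)
    return(structure(data.frame(name = character(), risk_class = character(),
                                may_cause_aki = logical(),
                                renally_cleared = logical(),
                                stringsAsFactors = FALSE),
                     class = c("aki_formulary", "data.frame")))
  df <- data.frame(
    name = normalize_drug(names(raw)),
    risk_class = vapply(raw, function(e)
      if (is.null(e$risk_class)) "other" else e$risk_class, character(1)),
    may_cause_aki = vapply(raw, function(e) isTRUE(e$may_cause_aki),
                           logical(1)),
    renally_cleared = vapply(raw, function(e) isTRUE(e$renally_cleared),
                             logical(1)),
    stringsAsFactors = FALSE, row.names = NULL)
  bad <- !df$risk_class %in% c(RISK_CLASSES, "other")
  if (any(bad))
    stop("unknown risk_class for: ", paste(df$name[bad], collapse = ", "),
         call. = FALSE)
  flagless <- !df$may_cause_aki & !df$renally_cleared
  if (any(flagless))
    stop("formulary entries with no true flag: ",
         paste(df$name[flagless], collapse = ", "), call. = FALSE)
  if (anyDuplicated(df$name))
    stop("duplicate formulary names after normalization", call. = FALSE)
  structure(df, class = c("aki_formulary", "data.frame"))
}

#' The packaged default formulary
#'
#' A representative per-class agent list (loop and thiazide diuretics,
#' nephrotoxic antibiotics, ACE inhibitors / ARBs, NSAIDs, and a few
#' renally cleared agents). It is a replaceable configuration file, not a
#' canonical institutional formulary; deployments substitute their own via
#' [read_formulary()].
#'
#' @return an `aki_formulary`.
#' @export
default_formulary <- function() {
  read_formulary(system.file("extdata", "default_formulary.json",
                             package = "akicds", mustWork = TRUE))
}

#' Classify one drug name against a formulary
#'
#' Names are normalized (case-folded, trimmed) before lookup; unknown
#' names classify as `other` with both flags false.
#'
#' @param drug_name free-text drug name.
#' @param formulary an `aki_formulary`.
#' @return list with `drug_class`, `may_cause_aki`, `renally_cleared`.
#' @export
classify_medication <- function(drug_name, formulary = default_formulary()) {
  key <- normalize_drug(drug_name)
  i <- match(key, formulary$name)
  if (is.na(i))
    return(list(drug_class = "other", may_cause_aki = FALSE,
                renally_cleared = FALSE))
  list(drug_class = formulary$risk_class[[i]],
       may_cause_aki = formulary$may_cause_aki[[i]],
       renally_cleared = formulary$renally_cleared[[i]])
}

#' Active may-cause-AKI medications at a point in time
#'
#' An order is active at `at` when `ordered_at <= at` and it has not been
#' discontinued by then (`at < discontinued_at`, or no discontinuation).
#' Only orders whose formulary entry has `may_cause_aki = TRUE` are
#' returned, in `ordered_at` order.
#'
#' @param orders medication-order data frame (`drug_name`, `ordered_at`,
#'   `discontinued_at`, ...).
#' @param at POSIXct query time.
#' @param formulary an `aki_formulary`.
#' @return the qualifying rows of `orders`, with `drug_class` attached.
#' @export
active_risk_medications <- function(orders, at,
                                    formulary = default_formulary()) {
  if (is.null(orders) || nrow(orders) == 0L) {
    out <- empty_meds(); out$drug_class <- character(); return(out)
  }
  prof <- lapply(orders$drug_name, classify_medication, formulary = formulary)
  risk <- vapply(prof, `[[`, logical(1), "may_cause_aki")
  active <- orders$ordered_at <= at &
    (is.na(orders$discontinued_at) | at < orders$discontinued_at)
  out <- orders[risk & active, , drop = FALSE]
  out$drug_class <- vapply(prof[risk & active], `[[`, character(1),
                           "drug_class")
  out <- out[order(out$ordered_at), , drop = FALSE]
  rownames(out) <- NULL
  out
}

empty_warnings <- function() data.frame(
  warning_id = character(), patient_id = character(),
  encounter_id = character(), drug_name = character(),
  drug_class = character(), ordered_at = na_time(0L),
  raised_at = na_time(0L), onset_at = na_time(0L),
  episode_index = integer(), aki_stage_at_order = integer(),
  unit_type = character(), overridden = logical(), stringsAsFactors = FALSE)

#' Check one medication order against an episode state
#'
#' The interruptive warning fires iff the patient is in an open AKI
#' episode, the order falls within `med_warning_window_hours` of episode
#' onset (closed interval: `onset_at <= ordered_at <= onset_at + window`),
#' and the drug may cause AKI. The warning never blocks the order; the
#' prescriber can always override.
#'
#' @param order a one-row medication order (`drug_name`, `ordered_at`).
#' @param episode episode state as of the order time: list with
#'   `in_episode`, `onset_at`, `max_alerted_stage`, `episode_index`.
#' @param formulary an `aki_formulary`.
#' @param config a [staging_config()].
#' @return a one-row warning data frame, or `NULL` when no warning is due.
#' @export
check_medication_order <- function(order, episode,
                                   formulary = default_formulary(),
                                   config = staging_config()) {
  if (!isTRUE(episode$in_episode)) return(NULL)
  prof <- classify_medication(order$drug_name[[1]], formulary)
  if (!prof$may_cause_aki) return(NULL)
  t <- order$ordered_at[[1]]
  onset <- episode$onset_at[[1]]
  if (t < onset) return(NULL)
  if (!config$warn_any_time_in_episode &&
      t > onset + hours(config$med_warning_window_hours)) return(NULL)
  data.frame(
    warning_id = sprintf("%s-w-%s", order$patient_id[[1]], format_ts(t)),
    patient_id = order$patient_id[[1]],
    encounter_id = if (!is.null(order$encounter_id)) order$encounter_id[[1]]
                   else NA_character_,
    drug_name = order$drug_name[[1]], drug_class = prof$drug_class,
    ordered_at = t, raised_at = t, onset_at = onset,
    episode_index = episode$episode_index,
    aki_stage_at_order = episode$max_alerted_stage,
    unit_type = NA_character_, overridden = FALSE,
    stringsAsFactors = FALSE)
}

#' Detect adverse-medication warnings across a cohort
#'
#' Reconstructs each patient's episode timeline from a [detect_alerts()]
#' result and checks every medication order against the episode state at
#' its order time. The stage attributed to a warning is the highest stage
#' alerted in the episode at or before the order time.
#'
#' @param cohort an [aki_cohort()].
#' @param detection result of [detect_alerts()] on the same cohort (run
#'   internally when omitted).
#' @inheritParams check_medication_order
#' @return warnings data frame (possibly empty), ordered by patient then
#'   order time.
#' @export
detect_warnings <- function(cohort, detection = NULL,
                            formulary = default_formulary(),
                            config = staging_config()) {
  if (is.null(detection)) detection <- detect_alerts(cohort, config, formulary)
  alerts <- detection$alerts
  episodes <- detection$episodes
  out <- list()
  for (k in seq_len(nrow(cohort$meds))) {
    order <- cohort$meds[k, , drop = FALSE]
    pid <- order$patient_id
    t <- order$ordered_at
    epi <- episodes[episodes$patient_id == pid &
                      episodes$onset_at <= t &
                      (is.na(episodes$recovery_at) | t < episodes$recovery_at),
                    , drop = FALSE]
    if (nrow(epi) == 0L) next
    epi <- epi[1L, ]
    ep_alerts <- alerts[alerts$patient_id == pid &
                          alerts$episode_index == epi$episode_index &
                          alerts$raised_at <= t, , drop = FALSE]
    state <- list(in_episode = TRUE, onset_at = epi$onset_at,
                  episode_index = epi$episode_index,
                  max_alerted_stage = if (nrow(ep_alerts))
                    max(ep_alerts$stage) else 0L)
    w <- check_medication_order(order, state, formulary, config)
    if (!is.null(w)) {
      w$unit_type <- encounter_unit_type(
        cohort$encounters[cohort$encounters$patient_id == pid, , drop = FALSE],
        w$encounter_id, t)
      out[[length(out) + 1L]] <- w
    }
  }
  res <- if (length(out)) do.call(rbind, out) else empty_warnings()
  rownames(res) <- NULL
  res
}

#' Write warnings as JSON-lines
#' @param warnings warnings data frame from [detect_warnings()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_warnings_jsonl <- function(warnings, path) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  for (i in seq_len(nrow(warnings))) {
    rec <- as.list(warnings[i, , drop = FALSE])
    for (nm in c("ordered_at", "raised_at", "onset_at"))
      rec[[nm]] <- format_ts(warnings[[nm]][[i]])
    rec <- rec[!vapply(rec, function(x) length(x) == 1L && is.na(x),
                       logical(1))]
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA), con)
  }
  invisible(path)
}
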