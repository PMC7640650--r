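# Silent-mode batch evaluation: run detection and the warning engine over
# a whole cohort with no display side effects and aggregate the audit
# frequency tables (alerts by stage / active medications / unit type;
# warnings by stage / medication class / unit type).

#' One-decimal percentage, half-away-from-zero
#'
#' `round()` in R rounds half to even; audit tables conventionally round
#' half away from zero (54/81 prints as 66.7). Zero totals yield `NA`.
#'
#' @param count,total nonnegative counts.
#' @return percentage rounded to one decimal, or `NA` when `total` is 0.
#' @export
percent_of <- function(count, total) {
  if (total == 0) return(NA_real_)
  x <- 100 * count / total
  sign(x) * floor(abs(x) * 10 + 0.5) / 10
}

#' Format a "count (percent)" table cell
#' @inheritParams percent_of
#' @return string like `"54 (66.7)"`; zero-total cells render
#'   `"0 (\u2014)"` (em dash).
#' @export
format_count_pct <- function(count, total) {
  p <- percent_of(count, total)
  if (is.na(p)) sprintf("%d (\u2014)", count)
  else sprintf("%d (%.1f)", count, p)
}

count_pct_table <- function(counts, total, levels) {
  counts <- counts[match(levels, names(counts))]
  counts[is.na(counts)] <- 0L
  data.frame(category = levels, count = as.integer(counts),
             percent = vapply(counts, percent_of, numeric(1),
                              total = total),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Build a silent-phase frequency report from raw counts
#'
#' The percentage and formatting rules live here so that printed audit
#' counts can be pushed through the exact arithmetic used for a live run.
#' All percentages use the relevant total (total alerts or total warnings)
#' as denominator.
#'
#' @param total_alerts total stage alerts.
#' @param alerts_by_stage named count vector (`"1"`,`"2"`,`"3"`).
#' @param alerts_with_active_meds number of alerts whose active
#'   may-cause-AKI medication list is non-empty.
#' @param active_meds_by_class named count vector over
#'   diuretic/antibiotic/acei_arb/nsaid (each distinct class counted at
#'   most once per alert).
#' @param alerts_by_unit_type named count vector over medical/surgical.
#' @param total_warnings total adverse-medication warnings.
#' @param warnings_by_stage,warnings_by_med_class,warnings_by_unit_type
#'   named count vectors for the warning table.
#' @return an object of class `cohort_report`.
#' @export
cohort_report_from_counts <- function(total_alerts = 0L,
                                      alerts_by_stage = c(),
                                      alerts_with_active_meds = 0L,
                                      active_meds_by_class = c(),
                                      alerts_by_unit_type = c(),
                                      total_warnings = 0L,
                                      warnings_by_stage = c(),
                                      warnings_by_med_class = c(),
                                      warnings_by_unit_type = c()) {
  structure(list(
    total_alerts = as.integer(total_alerts),
    alerts_by_stage = count_pct_table(alerts_by_stage, total_alerts,
                                      c("1", "2", "3")),
    alerts_with_active_meds = data.frame(
      count = as.integer(alerts_with_active_meds),
      percent = percent_of(alerts_with_active_meds, total_alerts)),
    active_meds_by_class = count_pct_table(active_meds_by_class,
                                           total_alerts, RISK_CLASSES),
    alerts_by_unit_type = count_pct_table(alerts_by_unit_type, total_alerts,
                                          UNIT_TYPES),
    total_warnings = as.integer(total_warnings),
    warnings_by_stage = count_pct_table(warnings_by_stage, total_warnings,
                                        c("1", "2", "3")),
    warnings_by_med_class = count_pct_table(warnings_by_med_class,
                                            total_warnings, RISK_CLASSES),
    warnings_by_unit_type = count_pct_table(warnings_by_unit_type,
                                            total_warnings, UNIT_TYPES)
  ), class = "cohort_report")
}

tab_count <- function(x, levels) {
  t <- table(factor(as.character(x), levels = levels))
  stats::setNames(as.integer(t), levels)
}

#' Aggregate alerts and warnings into a silent-phase report
#'
#' @param alerts alerts data frame ([detect_alerts()]).
#' @param warnings warnings data frame ([detect_warnings()]).
#' @return a `cohort_report`. An alert contributes to the
#'   alerts-with-active-medications row iff its at-risk medication list is
#'   non-empty; each distinct medication class contributes at most once per
#'   alert.
#' @export
cohort_report <- function(alerts, warnings) {
  class_counts <- stats::setNames(integer(length(RISK_CLASSES)),
                                  RISK_CLASSES)
  if (nrow(alerts)) {
    cls <- strsplit(alerts$risk_med_classes, ";", fixed = TRUE)
    for (cs in cls)
      for (c1 in intersect(unique(cs), RISK_CLASSES))
        class_counts[[c1]] <- class_counts[[c1]] + 1L
  }
  cohort_report_from_counts(
    total_alerts = nrow(alerts),
    alerts_by_stage = tab_count(alerts$stage, c("1", "2", "3")),
    alerts_with_active_meds = sum(alerts$n_risk_meds > 0),
    active_meds_by_class = class_counts,
    alerts_by_unit_type = tab_count(alerts$unit_type, UNIT_TYPES),
    total_warnings = nrow(warnings),
    warnings_by_stage = tab_count(warnings$aki_stage_at_order,
                                  c("1", "2", "3")),
    warnings_by_med_class = tab_count(warnings$drug_class, RISK_CLASSES),
    warnings_by_unit_type = tab_count(warnings$unit_type, UNIT_TYPES))
}

#' Run the silent-mode evaluation over a cohort
#'
#' Runs detection and the adverse-medication warning engine over every
#' patient with all display side effects suppressed, and aggregates the
#' audit report.
#'
#' @param cohort an [aki_cohort()].
#' @param config a [staging_config()].
#' @param formulary an `aki_formulary`.
#' @return list of class `silent_run` with `alerts`, `warnings`, `report`.
#' @export
run_silent <- function(cohort, config = staging_config(),
                       formulary = default_formulary()) {
  detection <- detect_alerts(cohort, config, formulary)
  warnings <- detect_warnings(cohort, detection, formulary, config)
  structure(list(alerts = detection$alerts, episodes = detection$episodes,
                 warnings = warnings,
                 report = cohort_report(detection$alerts, warnings)),
            class = "silent_run")
}

#' @export
print.silent_run <- function(x, ...) {
  cat(sprintf("<silent_run> %d alerts, %d warnings\n",
              x$report$total_alerts, x$report$total_warnings))
  print(x$report)
  invisible(x)
}

#' Render a report as a stable text table
#'
#' "N (P)" cells with one-decimal percentages, mirroring the silent-phase
#' audit tables; diff-able across runs.
#'
#' @param report a `cohort_report`.
#' @return character vector of table lines.
#' @export
format_report <- function(report) {
  cell <- function(count, total) format_count_pct(count, total)
  row <- function(label, count, total)
    sprintf("  %-42s %s", label, cell(count, total))
  stage_label <- function(s) sprintf("Stage %s AKI alerts", s)
  class_label <- c(diuretic = "Diuretics", antibiotic = "Antibiotics",
                   acei_arb = "ACE-I/ARB", nsaid = "NSAIDs")
  unit_label <- c(medical = "Medical unit", surgical = "Surgical unit")
  a <- report
  lines <- c(
    "AKI stage alerts",
    row("Total AKI alerts", a$total_alerts, a$total_alerts),
    vapply(seq_len(nrow(a$alerts_by_stage)), function(i)
      row(stage_label(a$alerts_by_stage$category[[i]]),
          a$alerts_by_stage$count[[i]], a$total_alerts), character(1)),
    row("Active medications included in AKI alerts",
        a$alerts_with_active_meds$count, a$total_alerts),
    vapply(seq_len(nrow(a$active_meds_by_class)), function(i)
      row(class_label[[a$active_meds_by_class$category[[i]]]],
          a$active_meds_by_class$count[[i]], a$total_alerts), character(1)),
    vapply(seq_len(nrow(a$alerts_by_unit_type)), function(i)
      row(unit_label[[a$alerts_by_unit_type$category[[i]]]],
          a$alerts_by_unit_type$count[[i]], a$total_alerts), character(1)),
    "",
    "AKI adverse medication warnings",
    row("Total AKI adverse medication warnings", a$total_warnings,
        a$total_warnings),
    vapply(seq_len(nrow(a$warnings_by_stage)), function(i)
      row(stage_label(a$warnings_by_stage$category[[i]]),
          a$warnings_by_stage$count[[i]], a$total_warnings), character(1)),
    vapply(seq_len(nrow(a$warnings_by_med_class)), function(i)
      row(class_label[[a$warnings_by_med_class$category[[i]]]],
          a$warnings_by_med_class$count[[i]], a$total_warnings),
      character(1)),
    vapply(seq_len(nrow(a$warnings_by_unit_type)), function(i)
      row(unit_label[[a$warnings_by_unit_type$category[[i]]]],
          a$warnings_by_unit_type$count[[i]], a$total_warnings),
      character(1)))
  lines
}

#' @export
print.cohort_report <- function(x, ...) {
  cat(format_report(x), sep = "\n")
  invisible(x)
}

#' Serialize a report to JSON
#' @param report a `cohort_report`.
#' @param path optional output file.
#' @return JSON string (invisibly when written).
#' @export
report_json <- function(report, path = NULL) {
  js <- jsonlite::toJSON(unclass(report), auto_unbox = TRUE, na = "null",
                         digits = NA, pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
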