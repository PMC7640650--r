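# Volume-status-branched order-set recommendation engine. The engine owns
# the branching structure (exactly one fluid strategy; a bolus always
# brings monitoring safety parameters); the order-item wording lives in an
# editable JSON template, since the deployed wording is an institutional
# document.

VOLUME_STATUSES <- c("hypovolemic", "euvolemic", "hypervolemic")

#' Load an order-set template
#'
#' @param path JSON template with fields `investigations` (`base`,
#'   `obstruction`), `fluid` (one item list per volume status),
#'   `monitoring` (`bolus`, `overload_risk`), `medication_review` (a
#'   pattern with `{drug}` and `{class}` placeholders), and `consults`
#'   (`pharmacy`, `nephrology_criteria`).
#' @return an object of class `aki_order_set`.
#' @export
read_order_set <- function(path) {
  tpl <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  needed <- c("investigations", "fluid", "monitoring", "medication_review",
              "consults")
  missing <- setdiff(needed, names(tpl))
  if (length(missing))
    stop("order-set template missing: ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (!all(VOLUME_STATUSES %in% names(tpl$fluid)) ||
      any(!vapply(tpl$fluid[VOLUME_STATUSES], length, integer(1))))
    stop("template must provide a non-empty fluid plan per volume status",
         call. = FALSE)
  if (length(tpl$monitoring$bolus) == 0L)
    stop("template must provide bolus monitoring items", call. = FALSE)
  structure(tpl, class = "aki_order_set")
}

#' The packaged default order-set template
#' @return an `aki_order_set`.
#' @export
default_order_set <- function() {
  read_order_set(system.file("extdata", "order_set_template.json",
                             package = "akicds", mustWork = TRUE))
}

#' Recommend AKI orders for a clinical assessment
#'
#' Branches on the assessed volume status: hypovolemic patients get IV
#' fluid bolus items with mandatory monitoring safety parameters (to catch
#' emerging volume overload during resuscitation), euvolemic patients get
#' maintenance IV fluids, hypervolemic patients get diuretic items.
#' Suspected obstruction adds renal-tract ultrasound guidance; a pharmacy
#' support request adds a pharmacy consult; every active at-risk medication
#' yields a review/hold item; nephrology-referral criteria from the
#' template populate the consult list.
#'
#' @param volume_status `"hypovolemic"`, `"euvolemic"` or
#'   `"hypervolemic"`.
#' @param overload_risk `TRUE` when the patient is judged at risk of
#'   developing volume overload (adds intensified monitoring items).
#' @param obstruction_suspected add ultrasound guidance.
#' @param wants_pharmacy_support add a pharmacy consult item.
#' @param active_risk_meds data frame of active at-risk medication orders
#'   (as from [active_risk_medications()]); one review item per order.
#' @param template an [read_order_set()] template.
#' @return an object of class `aki_order_rec`: lists `investigations`,
#'   `fluid_plan`, `monitoring`, `medication_actions`, `consults`, plus
#'   `fluid_strategy` (`bolus`/`maintenance`/`diuresis`).
#' @export
recommend_orders <- function(volume_status,
                             overload_risk = FALSE,
                             obstruction_suspected = FALSE,
                             wants_pharmacy_support = FALSE,
                             active_risk_meds = NULL,
                             template = default_order_set()) {
  if (length(volume_status) != 1L || !volume_status %in% VOLUME_STATUSES)
    stop("volume_status must be one of: ",
         paste(VOLUME_STATUSES, collapse = ", "), call. = FALSE)
  investigations <- as.character(template$investigations$base)
  if (isTRUE(obstruction_suspected))
    investigations <- c(investigations,
                        as.character(template$investigations$obstruction))
  fluid_plan <- as.character(template$fluid[[volume_status]])
  strategy <- switch(volume_status, hypovolemic = "bolus",
                     euvolemic = "maintenance", hypervolemic = "diuresis")
  monitoring <- character()
  if (strategy == "bolus") {
    monitoring <- as.character(template$monitoring$bolus)
    if (isTRUE(overload_risk))
      monitoring <- c(monitoring,
                      as.character(template$monitoring$overload_risk))
  }
  medication_actions <- character()
  if (!is.null(active_risk_meds) && nrow(active_risk_meds) > 0L) {
    cls <- if (!is.null(active_risk_meds$drug_class))
      active_risk_meds$drug_class else rep("", nrow(active_risk_meds))
    medication_actions <- vapply(seq_len(nrow(active_risk_meds)),
      function(i) {
        msg <- gsub("{drug}", active_risk_meds$drug_name[[i]],
                    template$medication_review, fixed = TRUE)
        gsub("{class}", cls[[i]], msg, fixed = TRUE)
      }, character(1))
  }
  consults <- as.character(template$consults$nephrology_criteria)
  if (isTRUE(wants_pharmacy_support))
    consults <- c(as.character(template$consults$pharmacy), consults)
  structure(list(volume_status = volume_status, fluid_strategy = strategy,
                 investigations = investigations, fluid_plan = fluid_plan,
                 monitoring = monitoring,
                 medication_actions = medication_actions,
                 consults = consults),
            class = "aki_order_rec")
}

#' @export
print.aki_order_rec <- function(x, ...) {
  cat(sprintf("<aki_order_rec> %s (%s strategy)\n", x$volume_status,
              x$fluid_strategy))
  section <- function(nm, items) {
    cat(" ", nm, ":\n", sep = "")
    if (length(items) == 0L) cat("    (none)\n")
    else for (it in items) cat("    - ", it, "\n", sep = "")
  }
  section("investigations", x$investigations)
  section("fluid plan", x$fluid_plan)
  section("monitoring", x$monitoring)
  section("medication actions", x$medication_actions)
  section("consults", x$consults)
  invisible(x)
}

#' Serialize a recommendation to JSON
#' @param rec an `aki_order_rec`.
#' @param path optional output file.
#' @return JSON string (invisibly when written).
#' @export
order_rec_json <- function(rec, path = NULL) {
  js <- jsonlite::toJSON(unclass(rec), auto_unbox = TRUE, pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
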