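# Internal time helpers. All timestamps in the package are POSIXct in UTC;
# on disk they are ISO-8601 strings ("2024-03-01T08:00:00Z").

#' Parse ISO-8601 timestamps to UTC POSIXct
#'
#' Accepts `YYYY-MM-DDTHH:MM:SS` with an optional trailing `Z`, or a plain
#' `YYYY-MM-DD HH:MM:SS`, or a bare date. Unparseable inputs become `NA`.
#'
#' @param x character vector of timestamps.
#' @return POSIXct vector in UTC.
#' @keywords internal
parse_ts <- function(x) {
  x <- as.character(x)
  out <- rep(as.POSIXct(NA), length(x))
  x2 <- sub("Z$", "", x)
  x2 <- sub("T", " ", x2, fixed = TRUE)
  has_time <- grepl("^\\d{4}-\\d{2}-\\d{2} \\d{2}:\\d{2}(:\\d{2})?$", x2)
  bare_date <- grepl("^\\d{4}-\\d{2}-\\d{2}$", x2)
  if (any(has_time))
    out[has_time] <- as.POSIXct(x2[has_time], tz = "UTC")
  if (any(bare_date))
    out[bare_date] <- as.POSIXct(paste0(x2[bare_date], " 00:00:00"),
                                 tz = "UTC")
  attr(out, "tzone") <- "UTC"
  out
}

#' Format UTC POSIXct as ISO-8601 strings
#' @param t POSIXct vector.
#' @return character vector like `"2024-03-01T08:00:00Z"`; `NA` stays `NA`.
#' @keywords internal
format_ts <- function(t) {
  out <- format(t, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  out[is.na(t)] <- NA_character_
  out
}

hours <- function(h) as.difftime(h, units = "hours")
days <- function(d) as.difftime(d, units = "days")

# snap to whole seconds (the on-disk format is second-resolution)
snap_s <- function(t) {
  as.POSIXct(round(as.numeric(t)), origin = "1970-01-01", tz = "UTC")
}

na_time <- function(n = 1L) {
  t <- rep(as.POSIXct(NA), n)
  attr(t, "tzone") <- "UTC"
  t
}
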