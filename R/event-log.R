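#' Read an event log CSV
#'
#' The event log is the package's exchange format for raw self-tracked data:
#' one row per event with columns `woman_id`, `date` (ISO-8601 YYYY-MM-DD),
#' `event` (`menses_onset` or `ovulation`) and `basis` (empty for onsets;
#' `clinical`, `test_kit` or `other` for ovulation records).
#'
#' @param path Path to a UTF-8 CSV file with a header row.
#' @return A data frame with columns `woman_id` (character), `date` (Date),
#'   `event` (character) and `basis` (character, `NA` for onsets).
#' @seealso [write_event_log()], [derive_cycles()]
#' @export
read_event_log <- function(path) {
  if (!file.exists(path)) {
    stop("event log file not found: ", path, call. = FALSE)
  }
  x <- read.csv(path, colClasses = "character", na.strings = "")
  required <- c("woman_id", "date", "event", "basis")
  missing <- setdiff(required, names(x))
  if (length(missing)) {
    stop("event log is missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  x <- x[required]
  x$date <- as.Date(x$date)
  if (anyNA(x$date)) stop("unparseable dates in event log", call. = FALSE)
  bad <- setdiff(unique(x$event), c("menses_onset", "ovulation"))
  if (length(bad)) {
    stop("unknown event type(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  ov <- x$event == "ovulation"
  if (anyNA(x$basis[ov]) || !all(x$basis[ov] %in% .basis_levels)) {
    stop("ovulation records must carry a basis in {",
         paste(.basis_levels, collapse = ", "), "}", call. = FALSE)
  }
  x$basis[!ov] <- NA_character_
  x
}

#' Write an event log CSV
#'
#' Rows are sorted by woman, date and event type before writing so that the
#' same data always produce a byte-identical file.
#'
#' @param events Data frame as returned by [read_event_log()] or
#'   [generate_population()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_event_log <- function(events, path) {
  ord <- order(events$woman_id, events$date, events$event)
  out <- events[ord, c("woman_id", "date", "event", "basis"), drop = FALSE]
  out$date <- format(out$date, "%Y-%m-%d")
  write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}
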