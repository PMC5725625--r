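# Build an event log for one woman from chronological cycle lengths.
# `f` (optional, aligned with `lengths`) adds an ovulation event f days
# after the cycle's starting onset.
event_log_for <- function(woman_id, lengths, f = NULL, basis = "test_kit",
                          start = as.Date("2020-01-01")) {
  onsets <- start + cumsum(c(0, lengths))
  ev <- data.frame(woman_id = woman_id, date = onsets,
                   event = "menses_onset", basis = NA_character_,
                   stringsAsFactors = FALSE)
  if (!is.null(f)) {
    keep <- !is.na(f)
    ov <- data.frame(woman_id = woman_id,
                     date = onsets[-length(onsets)][keep] + f[keep],
                     event = "ovulation",
                     basis = rep_len(basis, sum(keep)),
                     stringsAsFactors = FALSE)
    ev <- rbind(ev, ov)
  }
  ev
}

# Stack several women's logs
event_log_many <- function(...) do.call(rbind, list(...))

# Cycle table straight from chronological lengths (no screening surprises)
cycles_for <- function(woman_id, lengths, f = NULL, ...) {
  derive_cycles(event_log_for(woman_id, lengths, f, ...), lo = 1, hi = 1000)
}
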