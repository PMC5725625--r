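#' Derive menstrual cycles from menstruation onsets
#'
#' A woman with T recorded onsets yields T - 1 cycles. Cycles are indexed by
#' recency: cycle `j = 1` is the most recent, spanning the second most recent
#' onset (its `start_date`) to the most recent onset (its `end_date`), with
#' length `c = elapsed_days(end_date, start_date)`. Women with fewer than two
#' onsets contribute no cycles.
#'
#' @param onsets Data frame with columns `woman_id` and `date`; an event log
#'   is accepted, in which case only `menses_onset` rows are used.
#' @return A cycle table: data frame with columns `woman_id`, `j` (recency
#'   index, 1 = most recent), `start_date`, `end_date`, `c` (length, days),
#'   and empty phase columns `f`, `l`, `basis` to be filled by
#'   [attach_ovulation()].
#' @export
compute_cycles <- function(onsets) {
  if ("event" %in% names(onsets)) {
    onsets <- onsets[onsets$event == "menses_onset", , drop = FALSE]
  }
  w <- as.character(onsets$woman_id)
  d <- as.Date(onsets$date)
  ord <- order(w, -as.numeric(d))
  w <- w[ord]; d <- d[ord]
  n <- length(w)
  empty <- data.frame(
    woman_id = character(), j = integer(),
    start_date = as.Date(character()), end_date = as.Date(character()),
    c = integer(), f = integer(), l = integer(), basis = character(),
    stringsAsFactors = FALSE
  )
  if (n < 2) return(empty)
  same <- w[-n] == w[-1]
  if (any(same & d[-n] == d[-1])) {
    dup <- unique(w[-n][same & d[-n] == d[-1]])
    stop("duplicate onset dates for woman/women: ",
         paste(dup, collapse = ", "), call. = FALSE)
  }
  i <- which(same)  # row i is the end onset, row i + 1 the start onset
  if (!length(i)) return(empty)
  cyc <- data.frame(
    woman_id = w[i],
    j = as.integer(ave(rep(1L, length(i)), w[i], FUN = cumsum)),
    start_date = d[i + 1L],
    end_date = d[i],
    c = as.integer(d[i] - d[i + 1L]),
    f = NA_integer_, l = NA_integer_, basis = NA_character_,
    stringsAsFactors = FALSE
  )
  rownames(cyc) <- NULL
  cyc
}

#' Screen cycles on length
#'
#' Removes implausible cycles attributable to missed or erroneous logging.
#' Bounds are inclusive: cycles with `lo <= c <= hi` are kept. The operation
#' is idempotent and preserves row order (and the recency index `j`, so gaps
#' in `j` record where screening removed a cycle).
#'
#' @param cycles A cycle table from [compute_cycles()].
#' @param lo,hi Inclusive bounds in days (defaults 20 and 45).
#' @return The screened cycle table.
#' @export
screen_cycles <- function(cycles, lo = 20, hi = 45) {
  if (lo > hi) stop("screening bounds: lo > hi", call. = FALSE)
  out <- cycles[cycles$c >= lo & cycles$c <= hi, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Attach ovulation records to cycles
#'
#' For each ovulation record whose basis is allowed and whose date falls
#' strictly between a cycle's two onsets, sets the follicular phase length
#' `f = elapsed_days(ovulation, start_date)` and the luteal phase length
#' `l = c - f - 1` (the day after ovulation through the day before the next
#' onset). Records dated exactly on an onset are inconsistent input and are
#' discarded with a warning; records with a disallowed basis, or falling in
#' no retained cycle, are ignored. Never alters `c`.
#'
#' @param cycles A cycle table (typically already screened).
#' @param ovulations Data frame with columns `woman_id`, `date`, `basis`; an
#'   event log is accepted (only `ovulation` rows are used).
#' @param allowed_bases Basis labels that qualify; by default only
#'   `clinical` and `test_kit` records are trusted.
#' @param multiple Policy when two or more qualifying records fall inside
#'   one cycle: `"drop"` (default) leaves that cycle unannotated with a
#'   warning; `"earliest"` keeps the earliest record.
#' @return The cycle table with `f`, `l` and `basis` filled where a
#'   qualifying record exists.
#' @export
attach_ovulation <- function(cycles, ovulations,
                             allowed_bases = c("clinical", "test_kit"),
                             multiple = c("drop", "earliest")) {
  multiple <- match.arg(multiple)
  if ("event" %in% names(ovulations)) {
    ovulations <- ovulations[ovulations$event == "ovulation", , drop = FALSE]
  }
  if (!all(allowed_bases %in% .basis_levels)) {
    stop("allowed_bases must be a subset of {",
         paste(.basis_levels, collapse = ", "), "}", call. = FALSE)
  }
  bad <- !(ovulations$basis %in% .basis_levels)
  if (any(bad)) {
    stop("ovulation records with unknown basis", call. = FALSE)
  }
  ov <- ovulations[ovulations$basis %in% allowed_bases, , drop = FALSE]
  if (!nrow(ov) || !nrow(cycles)) return(cycles)
  ov$date <- as.Date(ov$date)
  ov$woman_id <- as.character(ov$woman_id)

  onset_key <- c(paste(cycles$woman_id, cycles$start_date),
                 paste(cycles$woman_id, cycles$end_date))
  on_onset <- paste(ov$woman_id, ov$date) %in% onset_key
  if (any(on_onset)) {
    warning(sum(on_onset),
            " ovulation record(s) dated on a menstruation onset discarded")
    ov <- ov[!on_onset, , drop = FALSE]
  }
  if (!nrow(ov)) return(cycles)

  cyc_by_woman <- split(seq_len(nrow(cycles)), cycles$woman_id)
  ov_by_woman <- split(ov, ov$woman_id)
  n_multi <- 0L
  for (wid in names(ov_by_woman)) {
    rows <- cyc_by_woman[[wid]]
    if (is.null(rows)) next
    cw <- cycles[rows, ]
    for (r in seq_len(nrow(ov_by_woman[[wid]]))) {
      o <- ov_by_woman[[wid]][r, ]
      hit <- which(cw$start_date < o$date & o$date < cw$end_date)
      if (!length(hit)) next
      idx <- rows[hit[1L]]
      f_new <- elapsed_days(o$date, cw$start_date[hit[1L]])
      if (!is.na(cycles$f[idx]) && cycles$f[idx] != f_new) {
        n_multi <- n_multi + 1L
        if (multiple == "drop") {
          cycles$f[idx] <- NA_integer_
          cycles$l[idx] <- NA_integer_
          cycles$basis[idx] <- "conflict"  # sentinel; cleared below
        } else if (f_new < cycles$f[idx]) {
          cycles$f[idx] <- f_new
          cycles$l[idx] <- cycles$c[idx] - f_new - 1L
          cycles$basis[idx] <- o$basis
        }
      } else if (is.na(cycles$f[idx]) && is.na(cycles$basis[idx])) {
        cycles$f[idx] <- f_new
        cycles$l[idx] <- cycles$c[idx] - f_new - 1L
        cycles$basis[idx] <- o$basis
      }
    }
  }
  if (n_multi > 0L) {
    warning(n_multi, " cycle(s) had multiple qualifying ovulation records (",
            if (multiple == "drop") "annotation dropped" else "kept earliest",
            ")")
  }
  cycles$basis[cycles$basis %in% "conflict"] <- NA_character_
  cycles
}

#' Trailing mean cycle length
#'
#' For each cycle `j` the trailing mean `c_star` is the mean length of the
#' `k` cycles immediately preceding it (recency indices `j + 1` to `j + k`).
#' It is the predictor used by every calendar method. All `k` past cycles
#' must exist *and have survived screening*; otherwise `c_star` is `NA` and
#' the cycle is excluded from k-specific analyses.
#'
#' @param cycles A (screened) cycle table.
#' @param k Number of past cycles to average (`k >= 1`).
#' @return `cycles` with an added numeric column `c_star`.
#' @export
add_trailing_mean <- function(cycles, k) {
  stopifnot(k >= 1)
  k <- as.integer(k)
  cycles$c_star <- NA_real_
  if (!nrow(cycles)) return(cycles)
  for (rows in split(seq_len(nrow(cycles)), cycles$woman_id)) {
    j <- cycles$j[rows]
    m <- max(j) + k
    present <- logical(m); present[j] <- TRUE
    val <- numeric(m); val[j] <- cycles$c[rows]
    cp <- cumsum(present); cv <- cumsum(val)
    ok <- cp[j + k] - cp[j] == k
    cycles$c_star[rows[ok]] <- (cv[j + k] - cv[j])[ok] / k
  }
  cycles
}

#' Mean length of the k cycles preceding cycle j
#'
#' Scalar convenience wrapper around [add_trailing_mean()] for a single
#' woman and target cycle.
#'
#' @param cycles A cycle table.
#' @param woman_id Woman identifier.
#' @param j Recency index of the target cycle.
#' @param k Number of past cycles averaged.
#' @return The trailing mean in days, or `NA` if the `k` past cycles are not
#'   all available.
#' @export
mean_cycle_length <- function(cycles, woman_id, j, k) {
  cw <- cycles[cycles$woman_id == woman_id, , drop = FALSE]
  cw <- add_trailing_mean(cw, k)
  out <- cw$c_star[cw$j == j]
  if (!length(out)) NA_real_ else out
}

#' Derive screened, annotated cycles from an event log
#'
#' Convenience composition of [compute_cycles()], [screen_cycles()] and
#' [attach_ovulation()] — the standard preprocessing applied before any
#' modelling. Screening is applied before ovulation attachment.
#'
#' @param events Event log data frame (see [read_event_log()]).
#' @param lo,hi Inclusive screening bounds in days.
#' @param allowed_bases,multiple Passed to [attach_ovulation()].
#' @return A screened cycle table with `f`, `l`, `basis` filled where an
#'   ovulation record qualifies.
#' @export
derive_cycles <- function(events, lo = 20, hi = 45,
                          allowed_bases = c("clinical", "test_kit"),
                          multiple = c("drop", "earliest")) {
  cyc <- compute_cycles(events)
  cyc <- screen_cycles(cyc, lo, hi)
  attach_ovulation(cyc, events, allowed_bases, multiple)
}
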