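#' Reference cohort phase-length summary
#'
#' Published per-cycle-length summary of a large Japanese cycle-tracking app
#' cohort (7043 women; 12,731 ovulation-dated cycles out of 135,666 logged):
#' for each integer cycle length 23-40 days, the number of ovulation-dated
#' cycles, the mean follicular and luteal phase lengths, and the 2.5-97.5
#' percentile ranges of the individual phase lengths. Shipped as a
#' plain-text table under `extdata`; used to calibrate [table1_preset()] and
#' for internal-consistency checks (the `n` column sums to the cohort's
#' ovulation-dated total and the count-weighted column means reproduce the
#' cohort's overall means).
#'
#' @return Data frame with columns `cycle_length`, `n`, `mean_follicular`,
#'   `f_lo`, `f_hi`, `mean_luteal`, `l_lo`, `l_hi`.
#' @export
cohort_phase_summary <- function() {
  read.csv(system.file("extdata", "cohort_phase_summary.csv",
                       package = "ovucal"))
}

#' Reference cohort record-depth counts
#'
#' For the same cohort as [cohort_phase_summary()]: the number of
#' ovulation-dated cycles that have at least `k` screened past cycles
#' (k = 1..8), broken down by integer mean-cycle-length bin. The published
#' per-bin rows cover bins 24-37 only and therefore do not sum to the
#' published totals, which are shipped as a separate `total` row and
#' returned separately here.
#'
#' @return List with `by_bin` (data frame: `mean_cycle_length`, `k1`..`k8`)
#'   and `totals` (named integer vector `k1`..`k8`).
#' @export
cohort_record_depth <- function() {
  x <- read.csv(system.file("extdata", "cohort_record_depth.csv",
                            package = "ovucal"),
                colClasses = c(mean_cycle_length = "character"))
  tot <- x$mean_cycle_length == "total"
  by_bin <- x[!tot, , drop = FALSE]
  by_bin$mean_cycle_length <- as.integer(by_bin$mean_cycle_length)
  rownames(by_bin) <- NULL
  totals <- unlist(x[tot, -1L])
  list(by_bin = by_bin, totals = totals)
}
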