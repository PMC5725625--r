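#' Elapsed days between two calendar dates
#'
#' Day-resolution difference `a - b`, the primitive all cycle and phase
#' lengths are built from. Antisymmetric: `elapsed_days(a, b) ==
#' -elapsed_days(b, a)`.
#'
#' @param a,b Dates (or anything `as.Date()` accepts). Recycled.
#' @return Integer vector of whole days.
#' @examples
#' elapsed_days("2020-01-29", "2020-01-01")  # 28
#' @export
elapsed_days <- function(a, b) {
  as.integer(as.Date(a) - as.Date(b))
}
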