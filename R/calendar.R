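#' Ogino calendar prediction of follicular phase length
#'
#' The Ogino rule assumes a fixed 14-day luteal phase, so the next ovulation
#' falls `floor(c_star) - 15` days after the previous menstruation onset
#' (ovulation day + 14 luteal days + 1 = cycle length). Brackets round down
#' to the nearest integer.
#'
#' @param c_star Mean length of past cycles, days (numeric vector).
#' @return Integer predicted follicular phase length.
#' @export
ogino_predict <- function(c_star) {
  if (any(c_star <= 15, na.rm = TRUE)) {
    stop("Ogino prediction is non-positive for mean cycle length <= 15 days",
         call. = FALSE)
  }
  as.integer(floor(c_star) - 15)
}

#' Half-cycle-length (HCL) prediction of follicular phase length
#'
#' Predicts the next ovulation at the middle of the mean cycle:
#' `floor(c_star / 2)` days after the previous onset.
#'
#' @inheritParams ogino_predict
#' @return Integer predicted follicular phase length.
#' @export
hcl_predict <- function(c_star) {
  if (any(c_star < 2, na.rm = TRUE)) {
    stop("HCL prediction requires mean cycle length >= 2 days", call. = FALSE)
  }
  as.integer(floor(c_star / 2))
}

#' Fit the optimized linear predictor for one k
#'
#' Builds the panel of `(c_star(k), f)` pairs over all ovulation-dated
#' cycles whose trailing mean is computable and fits the chosen panel
#' estimator (random-effect GLS by default). The resulting line
#' `alpha + beta * c_star`, floored, is the optimized calendar predictor for
#' that `k`. One fit is produced per `k`; fits are fitted in-sample on the
#' full dataset by default (see `holdout`), mirroring how such calendar
#' rules are derived from a whole cohort. An optional woman-level hold-out
#' is provided because in-sample evaluation optimistically biases the
#' optimized method.
#'
#' @param cycles A screened, ovulation-annotated cycle table.
#' @param k Number of past cycles averaged.
#' @param estimator Panel estimator: `"gls"` (default), `"pooled"`, `"lsdv"`.
#' @param holdout Fraction of women to withhold from fitting (0, the
#'   default, fits on everyone). Withheld women are recorded in
#'   `$holdout_women` so evaluation can be restricted to them.
#' @return An object of class `"optimized_fit"`: list with `k`, `alpha`,
#'   `beta`, `estimator`, `n_cycles`, `n_women`, `holdout_women` and the
#'   underlying `"panel_lm"` fit in `$fit`.
#' @export
fit_optimized <- function(cycles, k, estimator = c("gls", "pooled", "lsdv"),
                          holdout = 0) {
  estimator <- match.arg(estimator)
  stopifnot(holdout >= 0, holdout < 1)
  panel <- panel_for_k(cycles, k, target = "follicular")
  holdout_women <- character()
  if (holdout > 0) {
    women <- unique(panel$woman_id)
    holdout_women <- sample(women, ceiling(holdout * length(women)))
    panel <- panel[!(panel$woman_id %in% holdout_women), , drop = FALSE]
  }
  if (length(unique(panel$woman_id)) < 2L) {
    stop("need (c_star, f) pairs from at least 2 women", call. = FALSE)
  }
  fit <- panel_lm(y ~ x, panel, id = "woman_id", estimator = estimator)
  structure(
    list(k = as.integer(k),
         alpha = unname(coef(fit)[1L]), beta = unname(coef(fit)[2L]),
         estimator = estimator, n_cycles = fit$nobs,
         n_women = fit$n_women, holdout_women = holdout_women, fit = fit),
    class = "optimized_fit"
  )
}

#' @export
print.optimized_fit <- function(x, ...) {
  cat(sprintf(
    "Optimized calendar predictor (k = %d, %s): f = floor(%.4g + %.4g * c_star)\n",
    x$k, x$estimator, x$alpha, x$beta))
  cat(sprintf("  fitted on %d cycles from %d women\n", x$n_cycles, x$n_women))
  invisible(x)
}

#' Optimized prediction of follicular phase length
#'
#' Applies a fitted [fit_optimized()] line: `floor(alpha + beta * c_star)`.
#' Predictions below 1 day are invalid and returned as `NA` with a warning.
#'
#' @param fit An `"optimized_fit"`.
#' @param c_star Mean length of past cycles, days.
#' @return Integer predicted follicular phase length (`NA` where invalid).
#' @export
opt_predict <- function(fit, c_star) {
  stopifnot(inherits(fit, "optimized_fit"))
  mu <- as.integer(floor(fit$alpha + fit$beta * c_star))
  bad <- !is.na(mu) & mu < 1L
  if (any(bad)) {
    warning(sum(bad), " optimized prediction(s) below 1 day flagged invalid")
    mu[bad] <- NA_integer_
  }
  mu
}

#' Predict the next ovulation date
#'
#' All three calendar methods predict ovulation a method-specific number of
#' days after the onset of the previous menstruation.
#'
#' @param onset Date of the previous menstruation onset.
#' @param method `"ogino"`, `"hcl"` or `"opt"`.
#' @param c_star Mean length of past cycles, days.
#' @param fit An `"optimized_fit"` (required for `method = "opt"`; its `k`
#'   must match the `k` used to compute `c_star`).
#' @return Date vector of predicted ovulation dates (strictly after onset).
#' @export
predict_ovulation_date <- function(onset, method = c("ogino", "hcl", "opt"),
                                   c_star, fit = NULL) {
  method <- match.arg(method)
  mu <- switch(method,
    ogino = ogino_predict(c_star),
    hcl = hcl_predict(c_star),
    opt = {
      if (is.null(fit)) stop("method 'opt' requires a fit", call. = FALSE)
      opt_predict(fit, c_star)
    }
  )
  as.Date(onset) + mu
}
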