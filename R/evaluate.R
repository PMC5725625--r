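#' Build the k-specific panel of trailing means and phase lengths
#'
#' For a given `k`, selects the ovulation-dated cycles whose `k` past cycles
#' all exist post-screening and returns the `(x, y)` panel used by the
#' correlation, fitting and accuracy analyses, where `x = c_star(k)` and `y`
#' is the chosen target of the cycle itself. All targets are computed on the
#' ovulation-dated subset (including `"next_cycle"`), matching the
#' population the record-depth counts are defined on.
#'
#' @param cycles A screened, ovulation-annotated cycle table.
#' @param k Number of past cycles averaged.
#' @param target `"follicular"` (f), `"luteal"` (l) or `"next_cycle"` (c).
#' @return Data frame with columns `woman_id`, `j`, `x`, `y`.
#' @export
panel_for_k <- function(cycles, k,
                        target = c("follicular", "luteal", "next_cycle")) {
  target <- match.arg(target)
  cs <- add_trailing_mean(cycles, k)
  keep <- !is.na(cs$c_star) & !is.na(cs$f)
  cs <- cs[keep, , drop = FALSE]
  y <- switch(target, follicular = cs$f, luteal = cs$l, next_cycle = cs$c)
  data.frame(woman_id = cs$woman_id, j = cs$j, x = cs$c_star,
             y = as.numeric(y), stringsAsFactors = FALSE)
}

#' Phase-length summary by cycle length
#'
#' One row per integer cycle length present among the ovulation-dated
#' cycles: count, mean follicular and luteal phase lengths, and the central
#' 95% range (2.5-97.5 percentiles of individual values, rounded to whole
#' days). Because `l = c - f - 1` exactly, each row satisfies
#' `mean_f + mean_l + 1 == cycle_length`.
#'
#' @param cycles A screened, ovulation-annotated cycle table.
#' @return Data frame with columns `cycle_length`, `n`, `mean_follicular`,
#'   `f_lo`, `f_hi`, `mean_luteal`, `l_lo`, `l_hi`.
#' @export
summarize_by_cycle_length <- function(cycles) {
  sub <- cycles[!is.na(cycles$f), , drop = FALSE]
  rows <- lapply(split(sub, sub$c), function(d) {
    qf <- quantile(d$f, c(0.025, 0.975), names = FALSE)
    ql <- quantile(d$l, c(0.025, 0.975), names = FALSE)
    data.frame(cycle_length = d$c[1L], n = nrow(d),
               mean_follicular = mean(d$f),
               f_lo = round(qf[1L]), f_hi = round(qf[2L]),
               mean_luteal = mean(d$l),
               l_lo = round(ql[1L]), l_hi = round(ql[2L]))
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$cycle_length), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Record-depth counts of ovulation-dated cycles
#'
#' For each `k` up to `k_max`, counts the ovulation-dated cycles whose `k`
#' past cycles all exist post-screening, by integer mean-cycle-length bin
#' (nearest-integer rounding of `c_star(k)`). Because the k+1 requirement
#' nests inside the k requirement, per-k totals are non-increasing in `k`.
#'
#' @param cycles A screened, ovulation-annotated cycle table.
#' @param k_max Largest k (default 8).
#' @return Data frame with columns `k`, `bin`, `n`. Per-k totals are
#'   `tapply(out$n, out$k, sum)`.
#' @export
past_record_counts <- function(cycles, k_max = 8) {
  out <- lapply(seq_len(k_max), function(k) {
    p <- panel_for_k(cycles, k, target = "follicular")
    if (!nrow(p)) return(NULL)
    tab <- table(round(p$x))
    data.frame(k = k, bin = as.integer(names(tab)),
               n = as.integer(tab))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Correlation between trailing mean cycle length and a cycle outcome
#'
#' Pearson correlation between `c_star(k)` and the target quantity of the
#' same cycle, with the two-sided p-value from the exact t transform on
#' n - 2 degrees of freedom.
#'
#' @inheritParams panel_for_k
#' @return List with `r`, `p_value`, `n`.
#' @export
correlation_with_mean <- function(cycles, k,
                                  target = c("follicular", "luteal",
                                             "next_cycle")) {
  p <- panel_for_k(cycles, k, target)
  if (nrow(p) < 3L) stop("need at least 3 pairs", call. = FALSE)
  if (sd(p$x) == 0 || sd(p$y) == 0) {
    stop("undefined correlation: zero variance", call. = FALSE)
  }
  ct <- cor.test(p$x, p$y)
  list(r = unname(ct$estimate), p_value = ct$p.value, n = nrow(p))
}

#' Per-k panel fits with Hausman tests
#'
#' For each `k` and each phase-length target, fits the requested estimator
#' and runs the Hausman test comparing the within (LSDV) and random-effect
#' (GLS) slopes on the same panel.
#'
#' @param cycles A screened, ovulation-annotated cycle table.
#' @param k_range Integer vector of k values (default `1:8`).
#' @param targets Subset of `c("follicular", "luteal")`.
#' @param estimator Estimator whose coefficients are reported.
#' @param hausman_rule Decision rule, see [hausman_test()].
#' @return Data frame with columns `target`, `k`, `alpha`, `beta`, `H`,
#'   `p_value`, `favored`, `n_cycles`, `n_women`.
#' @export
per_k_fits <- function(cycles, k_range = 1:8,
                       targets = c("follicular", "luteal"),
                       estimator = c("gls", "pooled", "lsdv"),
                       hausman_rule = c("as_published", "standard")) {
  estimator <- match.arg(estimator)
  hausman_rule <- match.arg(hausman_rule)
  targets <- match.arg(targets, several.ok = TRUE)
  rows <- list()
  for (target in targets) {
    for (k in k_range) {
      panel <- panel_for_k(cycles, k, target)
      fit <- panel_lm(y ~ x, panel, id = "woman_id", estimator = estimator)
      fixed <- panel_lm(y ~ x, panel, id = "woman_id", estimator = "lsdv")
      random <- if (estimator == "gls") fit else {
        panel_lm(y ~ x, panel, id = "woman_id", estimator = "gls")
      }
      h <- hausman_test(fixed, random, rule = hausman_rule)
      rows[[length(rows) + 1L]] <- data.frame(
        target = target, k = k,
        alpha = unname(coef(fit)[1L]), beta = unname(coef(fit)[2L]),
        H = h$statistic, p_value = h$p.value, favored = h$favored,
        n_cycles = fit$nobs, n_women = fit$n_women,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Prediction accuracy by mean-cycle-length bin
#'
#' Evaluates one calendar method at one allowable error `e` and one `k`:
#' for each integer bin of `c_star(k)` (nearest-integer rounding), the
#' fraction of ovulation-dated cycles whose predicted follicular length is
#' within `e` days of the observed one, `|mu - f| <= e`. Empty bins are
#' omitted. Invalid (NA) predictions count as incorrect.
#'
#' @param cycles A screened, ovulation-annotated cycle table.
#' @param method `"ogino"`, `"hcl"` or `"opt"`.
#' @param e Allowable error in days (0, 1 or 2 in the standard evaluation).
#' @param k Number of past cycles averaged.
#' @param fit An `"optimized_fit"` (required when `method = "opt"`; its `k`
#'   must match). If it was fitted with a hold-out, evaluation is
#'   restricted to the held-out women.
#' @return Data frame with columns `method`, `k`, `e`, `bin`, `n`,
#'   `accuracy`.
#' @export
accuracy_by_mean_cycle <- function(cycles, method = c("ogino", "hcl", "opt"),
                                   e = 0, k = 1, fit = NULL) {
  method <- match.arg(method)
  stopifnot(e >= 0)
  p <- panel_for_k(cycles, k, target = "follicular")
  if (method == "opt") {
    if (is.null(fit)) stop("method 'opt' requires a fit", call. = FALSE)
    if (fit$k != k) {
      stop("fit was made for k = ", fit$k, ", not k = ", k, call. = FALSE)
    }
    if (length(fit$holdout_women)) {
      p <- p[p$woman_id %in% fit$holdout_women, , drop = FALSE]
    }
  }
  mu <- switch(method,
    ogino = ogino_predict(p$x),
    hcl = hcl_predict(p$x),
    opt = opt_predict(fit, p$x)
  )
  correct <- !is.na(mu) & abs(mu - p$y) <= e
  bin <- round(p$x)
  agg <- aggregate(correct, by = list(bin = bin),
                   FUN = function(z) c(n = length(z), acc = mean(z)))
  data.frame(method = method, k = as.integer(k), e = e,
             bin = agg$bin, n = as.integer(agg$x[, "n"]),
             accuracy = agg$x[, "acc"], stringsAsFactors = FALSE)
}

#' Mean accuracy across mean-cycle-length bins
#'
#' Collapses accuracy cells to one value per `(method, e, k)`. The default
#' is the unweighted mean across bins, treating each mean-cycle-length bin
#' as one unit regardless of how many cycles fall in it; `pooled = TRUE`
#' computes the cycle-weighted pooled accuracy instead.
#'
#' @param cells Output of [accuracy_by_mean_cycle()] (rows from several
#'   calls may be concatenated).
#' @param pooled Weight bins by their cycle counts.
#' @return Data frame with columns `method`, `e`, `k`, `mean_accuracy`.
#' @export
mean_accuracy <- function(cells, pooled = FALSE) {
  f <- if (pooled) {
    function(d) weighted.mean(d$accuracy, d$n)
  } else {
    function(d) mean(d$accuracy)
  }
  key <- interaction(cells$method, cells$e, cells$k, drop = TRUE)
  rows <- lapply(split(cells, key), function(d) {
    data.frame(method = d$method[1L], e = d$e[1L], k = d$k[1L],
               mean_accuracy = f(d), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$method, out$e, out$k), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Evaluate calendar methods head-to-head
#'
#' Runs the full accuracy comparison: fits the optimized predictor per `k`
#' (when requested), evaluates every `(method, e, k)` combination with
#' [accuracy_by_mean_cycle()], and summarizes with [mean_accuracy()].
#'
#' @param cycles A screened, ovulation-annotated cycle table.
#' @param methods Methods to compare.
#' @param errors Allowable errors in days.
#' @param k_range k values.
#' @param estimator Estimator for the optimized fits.
#' @param pooled Passed to [mean_accuracy()].
#' @return List with `cells` (per-bin accuracies), `mean` (per method/e/k)
#'   and `fits` (the per-k optimized fits, if any).
#' @export
evaluate_accuracy <- function(cycles, methods = c("ogino", "hcl", "opt"),
                              errors = 0:2, k_range = 1:8,
                              estimator = c("gls", "pooled", "lsdv"),
                              pooled = FALSE) {
  estimator <- match.arg(estimator)
  fits <- if ("opt" %in% methods) {
    setNames(lapply(k_range, function(k)
      fit_optimized(cycles, k, estimator = estimator)),
      paste0("k", k_range))
  }
  cells <- list()
  for (method in methods) {
    for (e in errors) {
      for (k in k_range) {
        cells[[length(cells) + 1L]] <- accuracy_by_mean_cycle(
          cycles, method, e = e, k = k,
          fit = if (method == "opt") fits[[paste0("k", k)]])
      }
    }
  }
  cells <- do.call(rbind, cells)
  list(cells = cells, mean = mean_accuracy(cells, pooled = pooled),
       fits = fits)
}

#' Plot accuracy curves by mean cycle length
#'
#' One panel per allowable error, accuracy against mean-cycle-length bin,
#' one line per method.
#'
#' @param cells Accuracy cells from [evaluate_accuracy()] or
#'   [accuracy_by_mean_cycle()], all at one `k`.
#' @param ... Passed to [plot()].
#' @return `cells`, invisibly.
#' @export
plot_accuracy <- function(cells, ...) {
  errors <- sort(unique(cells$e))
  methods <- unique(cells$method)
  cols <- setNames(c("black", "red3", "blue3")[seq_along(methods)], methods)
  op <- par(mfrow = c(1, length(errors)))
  on.exit(par(op))
  for (e in errors) {
    d <- cells[cells$e == e, ]
    plot(range(d$bin), c(0, 1), type = "n",
         xlab = "mean cycle length (days)", ylab = "accuracy",
         main = paste0("allowable error ±", e, " d"), ...)
    for (method in methods) {
      dm <- d[d$method == method, ]
      dm <- dm[order(dm$bin), ]
      points(dm$bin, dm$accuracy, type = "b", col = cols[method], pch = 16)
    }
    legend("topright", legend = methods, col = cols, lty = 1, pch = 16,
           bty = "n")
  }
  invisible(cells)
}
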