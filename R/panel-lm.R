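#' Panel linear model with one covariate
#'
#' Fits `y ~ x` on grouped (panel) data by one of three estimators:
#'
#' * `"pooled"` — ordinary least squares ignoring the grouping;
#' * `"lsdv"` — the fixed-effect (least squares dummy variables / within)
#'   estimator: the slope comes from within-woman variation only, and each
#'   woman gets her own intercept `alpha_i = ybar_i - xbar_i * beta`;
#' * `"gls"` — random-effect generalized least squares under compound
#'   symmetry: residual covariance `xi_alpha + xi_eps` on the diagonal and
#'   `xi_alpha` off-diagonal within a woman, independent across women. The
#'   variance components are moment estimates from the pooled residuals
#'   (see [variance_components()]) and the GLS solution is computed by
#'   quasi-demeaning, which is algebraically identical to weighting by the
#'   block inverse of the compound-symmetric covariance.
#'
#' @param formula A two-sided formula with exactly one covariate,
#'   e.g. `f ~ c_star`.
#' @param data Data frame containing the model variables and the id column.
#' @param id Name of the grouping (woman) column in `data`, or a vector of
#'   group labels of the same length as `nrow(data)`.
#' @param estimator One of `"gls"` (default), `"pooled"`, `"lsdv"`.
#' @param components Optional list with elements `xi_alpha` and `xi_eps`
#'   overriding the estimated variance components (GLS only). Useful for
#'   sensitivity analyses and for checking the pooled and within limits.
#' @return An object of class `"panel_lm"` with methods for `print`,
#'   `summary`, `coef`, `predict`, `residuals`, `fitted`, `simulate` and
#'   `plot`. For `"lsdv"` the reported intercept is the mean of the
#'   per-woman intercepts, which are kept in `$woman_effects`.
#' @examples
#' p <- recovery_panel(alpha = 2, beta = 0.5, sigma_alpha = 1,
#'                     sigma_eps = 1, n_women = 50, T = 4, seed = 1)
#' fit <- panel_lm(y ~ x, p, id = "woman_id", estimator = "gls")
#' coef(fit)
#' @export
panel_lm <- function(formula, data, id = "woman_id",
                     estimator = c("gls", "pooled", "lsdv"),
                     components = NULL) {
  estimator <- match.arg(estimator)
  mf <- model.frame(formula, data, na.action = NULL)
  if (ncol(mf) != 2L) {
    stop("panel_lm() fits exactly one covariate: y ~ x", call. = FALSE)
  }
  y <- mf[[1L]]
  x <- mf[[2L]]
  g <- if (is.character(id) && length(id) == 1L) {
    if (is.null(data[[id]])) stop("id column '", id, "' not found in data",
                                  call. = FALSE)
    data[[id]]
  } else id
  ok <- complete.cases(y, x, g)
  y <- as.numeric(y[ok]); x <- as.numeric(x[ok]); g <- factor(g[ok])
  n <- length(y)
  if (n < 3L) stop("need at least 3 complete observations", call. = FALSE)
  if (length(unique(x)) < 2L) {
    stop("singular design: covariate is constant", call. = FALSE)
  }
  Ti <- tabulate(g)
  xname <- colnames(mf)[2L]
  yname <- colnames(mf)[1L]

  res <- switch(estimator,
    pooled = .fit_pooled(y, x),
    lsdv = .fit_lsdv(y, x, g),
    gls = .fit_gls(y, x, g, Ti, components)
  )
  names(res$coefficients) <- c("(Intercept)", xname)
  fitted <- res$coefficients[1L] +
    res$coefficients[2L] * x +
    if (estimator == "lsdv") {
      res$woman_effects[as.character(g)] - res$coefficients[1L]
    } else 0
  fitted <- unname(fitted)
  structure(
    list(
      coefficients = res$coefficients,
      estimator = estimator,
      residuals = y - fitted,
      fitted.values = fitted,
      woman_effects = res$woman_effects,
      components = res$components,
      vcov = res$vcov,
      sigma2 = res$sigma2,
      df.residual = res$df.residual,
      groups = g,
      T_i = setNames(Ti, levels(g)),
      nobs = n,
      n_women = nlevels(g),
      x = x, y = y,
      xname = xname, yname = yname,
      formula = formula,
      call = match.call()
    ),
    class = "panel_lm"
  )
}

.fit_pooled <- function(y, x) {
  fit <- lm.fit(cbind(1, x), y)
  b <- unname(fit$coefficients)
  r <- y - b[1L] - b[2L] * x
  s2 <- sum(r^2) / (length(y) - 2L)
  list(coefficients = b, woman_effects = NULL, components = NULL,
       vcov = s2 * chol2inv(fit$qr$qr[1:2, 1:2, drop = FALSE]),
       sigma2 = s2, df.residual = length(y) - 2L)
}

.fit_lsdv <- function(y, x, g) {
  xb <- ave(x, g); yb <- ave(y, g)
  sxx <- sum((x - xb)^2)
  if (sxx <= 0) {
    stop("singular design: no within-woman variation in the covariate",
         call. = FALSE)
  }
  beta <- sum((x - xb) * (y - yb)) / sxx
  ai <- tapply(y, g, mean) - beta * tapply(x, g, mean)
  r <- y - beta * x - ai[as.character(g)]
  dfr <- length(y) - nlevels(g) - 1L
  s2 <- sum(r^2) / max(dfr, 1L)
  list(coefficients = c(mean(ai), beta),
       woman_effects = setNames(as.numeric(ai), names(ai)),
       components = NULL,
       vcov = matrix(c(NA, NA, NA, s2 / sxx), 2L, 2L),
       sigma2 = s2, df.residual = dfr)
}

.fit_gls <- function(y, x, g, Ti, components) {
  pooled <- .fit_pooled(y, x)
  r <- y - pooled$coefficients[1L] - pooled$coefficients[2L] * x
  comp <- if (is.null(components)) {
    .variance_components(r, g, p = 2L)
  } else {
    list(xi_mu = components$xi_alpha + components$xi_eps,
         xi_alpha = components$xi_alpha, xi_eps = components$xi_eps)
  }
  if (comp$xi_eps <= 0 && any(Ti >= 2L)) {
    stop("degenerate covariance: within-woman variance is zero",
         call. = FALSE)
  }
  theta <- 1 - sqrt(comp$xi_eps / (comp$xi_eps + Ti * comp$xi_alpha))
  th <- theta[as.integer(g)]
  xb <- ave(x, g); yb <- ave(y, g)
  Xs <- cbind(1 - th, x - th * xb)
  ys <- y - th * yb
  fit <- lm.fit(Xs, ys)
  b <- unname(fit$coefficients)
  list(coefficients = b, woman_effects = NULL,
       components = comp,
       vcov = comp$xi_eps * chol2inv(fit$qr$qr[1:2, 1:2, drop = FALSE]),
       sigma2 = comp$xi_eps, df.residual = length(y) - 2L)
}

# moment estimator of the compound-symmetry variance components from
# pooled residuals; p = number of regression parameters
.variance_components <- function(r, g, p = 2L) {
  Ti <- tabulate(g)
  d1 <- length(r) - p
  d2 <- sum(Ti * (Ti - 1) / 2) - p
  if (d1 <= 0 || d2 <= 0) {
    stop("insufficient data to estimate variance components", call. = FALSE)
  }
  s <- tapply(r, g, sum)
  s2 <- tapply(r^2, g, sum)
  xi_mu <- sum(r^2) / d1
  xi_alpha <- sum(s^2 - s2) / 2 / d2
  if (xi_alpha < 0) {
    warning("negative between-woman variance estimate clamped to 0")
    xi_alpha <- 0
  }
  list(xi_mu = xi_mu, xi_alpha = xi_alpha,
       xi_eps = max(xi_mu - xi_alpha, 0))
}

#' Compound-symmetry variance components
#'
#' Moment estimates from pooled OLS residuals: `xi_mu` is the total residual
#' variance (sum of squared residuals over `sum(T_i) - p`); `xi_alpha` the
#' between-woman component (sum of within-woman residual cross-products over
#' `sum(T_i (T_i - 1) / 2) - p`); and `xi_eps = xi_mu - xi_alpha` the
#' within-woman component. Negative `xi_alpha` estimates (possible in small
#' samples) are clamped to zero with a warning, as is `xi_eps`.
#'
#' @param object A `"panel_lm"` fit. A pooled fit is used directly; a GLS
#'   fit returns its stored components; an LSDV fit is refused (components
#'   are defined on pooled residuals).
#' @return List with elements `xi_mu`, `xi_alpha`, `xi_eps` (days squared
#'   when the response is in days).
#' @export
variance_components <- function(object) {
  stopifnot(inherits(object, "panel_lm"))
  switch(object$estimator,
    pooled = .variance_components(object$residuals, object$groups, p = 2L),
    gls = object$components,
    stop("variance components are defined on pooled residuals; ",
         "fit with estimator = 'pooled' or 'gls'", call. = FALSE)
  )
}

#' Hausman specification test
#'
#' Compares the fixed-effect (within) and random-effect (GLS) slope
#' estimates. The statistic is the squared difference
#' `H = (beta_gls - beta_lsdv)^2`, referred to a chi-squared distribution
#' with one degree of freedom (upper tail), with no variance normalization —
#' exactly the form used in the analysis this package reproduces.
#'
#' Two decision rules are available. The default, `"as_published"`, rejects
#' the random-effect model when the p-value exceeds 0.05; note this is the
#' *reverse* of conventional practice (ordinarily a small p-value signals
#' disagreement between the estimators and hence rejects the random-effect
#' model), and `rule = "standard"` selects the conventional direction.
#'
#' @param fixed A `"panel_lm"` fit with `estimator = "lsdv"`.
#' @param random A `"panel_lm"` fit with `estimator = "gls"`.
#' @param rule `"as_published"` (default) or `"standard"`.
#' @return An object of class `"hausman_test"` with elements `statistic`,
#'   `p.value`, `favored` (`"fixed"` or `"random"`) and `rule`.
#' @export
hausman_test <- function(fixed, random, rule = c("as_published", "standard")) {
  rule <- match.arg(rule)
  stopifnot(inherits(fixed, "panel_lm"), inherits(random, "panel_lm"))
  if (fixed$estimator != "lsdv" || random$estimator != "gls") {
    stop("hausman_test() expects an lsdv fit and a gls fit", call. = FALSE)
  }
  if (fixed$nobs != random$nobs) {
    warning("fits appear to be on different panels (nobs differ)")
  }
  H <- unname((coef(random)[2L] - coef(fixed)[2L])^2)
  p <- pchisq(H, df = 1, lower.tail = FALSE)
  favored <- if (rule == "as_published") {
    if (p > 0.05) "fixed" else "random"
  } else {
    if (p < 0.05) "fixed" else "random"
  }
  structure(
    list(statistic = H, p.value = p, favored = favored, rule = rule,
         beta_fixed = unname(coef(fixed)[2L]),
         beta_random = unname(coef(random)[2L])),
    class = "hausman_test"
  )
}

#' @export
print.hausman_test <- function(x, ...) {
  cat("Hausman specification test (unnormalized)\n")
  cat(sprintf("  H = (beta_gls - beta_lsdv)^2 = %.6g, p = %.4g [chisq(1)]\n",
              x$statistic, x$p.value))
  cat(sprintf("  rule = %s; favored model: %s effects\n", x$rule, x$favored))
  invisible(x)
}

#' @export
print.panel_lm <- function(x, ...) {
  cat("Panel linear model (", x$estimator, ")\n", sep = "")
  cat("  ", deparse(x$formula), " on ", x$nobs, " obs from ",
      x$n_women, " women\n", sep = "")
  cat("Coefficients:\n")
  print(x$coefficients)
  if (!is.null(x$components)) {
    cat(sprintf("Variance components: xi_alpha = %.4g, xi_eps = %.4g\n",
                x$components$xi_alpha, x$components$xi_eps))
  }
  invisible(x)
}

#' @export
summary.panel_lm <- function(object, ...) {
  se <- sqrt(diag(object$vcov))
  est <- object$coefficients
  tval <- est / se
  pval <- 2 * pt(abs(tval), df = object$df.residual, lower.tail = FALSE)
  tab <- cbind(Estimate = est, `Std. Error` = se,
               `t value` = tval, `Pr(>|t|)` = pval)
  structure(
    list(call = object$call, estimator = object$estimator,
         coefficients = tab, components = object$components,
         nobs = object$nobs, n_women = object$n_women,
         sigma2 = object$sigma2, df.residual = object$df.residual),
    class = "summary.panel_lm"
  )
}

#' @export
print.summary.panel_lm <- function(x, ...) {
  cat("Panel linear model, estimator =", x$estimator, "\n")
  cat("Observations:", x$nobs, " Women:", x$n_women, "\n\n")
  stats::printCoefmat(x$coefficients, na.print = "-")
  if (!is.null(x$components)) {
    cat(sprintf(
      "\nVariance components: xi_mu = %.4g, xi_alpha = %.4g, xi_eps = %.4g\n",
      x$components$xi_mu, x$components$xi_alpha, x$components$xi_eps))
  }
  invisible(x)
}

#' @export
coef.panel_lm <- function(object, ...) object$coefficients

#' @export
residuals.panel_lm <- function(object, ...) object$residuals

#' @export
fitted.panel_lm <- function(object, ...) object$fitted.values

#' Predict from a panel linear model
#'
#' Population-level prediction `alpha + beta * x`. For an LSDV fit, if
#' `newdata` carries the id column and `use_woman_effects = TRUE`, known
#' women get their own intercept.
#'
#' @param object A `"panel_lm"` fit.
#' @param newdata Data frame with the covariate column (same name as in the
#'   fitting formula). `NULL` returns fitted values.
#' @param id Name of the id column in `newdata` (LSDV only).
#' @param use_woman_effects Use per-woman intercepts where available.
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @export
predict.panel_lm <- function(object, newdata = NULL, id = "woman_id",
                             use_woman_effects = FALSE, ...) {
  if (is.null(newdata)) return(object$fitted.values)
  xv <- newdata[[object$xname]]
  if (is.null(xv)) {
    stop("newdata must contain column '", object$xname, "'", call. = FALSE)
  }
  out <- object$coefficients[1L] + object$coefficients[2L] * as.numeric(xv)
  if (use_woman_effects && object$estimator == "lsdv" &&
      !is.null(newdata[[id]])) {
    ai <- object$woman_effects[as.character(newdata[[id]])]
    known <- !is.na(ai)
    out[known] <- ai[known] + object$coefficients[2L] * as.numeric(xv)[known]
  }
  unname(out)
}

#' Simulate responses from a fitted panel model
#'
#' Draws new response vectors at the observed covariate values. A GLS fit
#' simulates from the estimated random-effect model (new woman effects with
#' variance `xi_alpha`, noise with variance `xi_eps`); a pooled fit uses
#' i.i.d. noise at the residual variance; an LSDV fit keeps the estimated
#' woman intercepts fixed and redraws within-woman noise.
#'
#' @param object A `"panel_lm"` fit.
#' @param nsim Number of simulated response vectors.
#' @param seed Optional integer seed.
#' @param ... Unused.
#' @return Data frame with `nsim` columns `sim_1`, `sim_2`, ...
#' @export
simulate.panel_lm <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  n <- object$nobs
  g <- object$groups
  mu <- switch(object$estimator,
    lsdv = object$woman_effects[as.character(g)] +
      object$coefficients[2L] * object$x,
    object$coefficients[1L] + object$coefficients[2L] * object$x
  )
  out <- vapply(seq_len(nsim), function(s) {
    eps <- if (object$estimator == "gls") {
      a <- rnorm(nlevels(g), 0, sqrt(object$components$xi_alpha))
      a[as.integer(g)] + rnorm(n, 0, sqrt(object$components$xi_eps))
    } else {
      rnorm(n, 0, sqrt(object$sigma2))
    }
    as.numeric(mu + eps)
  }, numeric(n))
  out <- as.data.frame(out)
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' Plot a panel linear model fit
#'
#' Panel 1: observations with the population regression line. Panel 2:
#' residuals against fitted values.
#'
#' @param x A `"panel_lm"` fit.
#' @param which Which panels to draw (subset of `1:2`).
#' @param ... Passed to [plot()].
#' @return `x`, invisibly.
#' @export
plot.panel_lm <- function(x, which = 1:2, ...) {
  if (length(which) > 1L) {
    op <- par(mfrow = c(1, length(which)))
    on.exit(par(op))
  }
  if (1L %in% which) {
    plot(x$x, x$y, xlab = x$xname, ylab = x$yname,
         main = paste0("panel_lm (", x$estimator, ")"),
         col = "grey40", ...)
    abline(x$coefficients[1L], x$coefficients[2L], col = "red3", lwd = 2)
  }
  if (2L %in% which) {
    plot(x$fitted.values, x$residuals, xlab = "fitted", ylab = "residuals",
         main = "residuals vs fitted", col = "grey40", ...)
    abline(h = 0, lty = 2)
  }
  invisible(x)
}
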