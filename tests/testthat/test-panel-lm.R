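test_that("pooled OLS matches closed-form simple regression", {
  d <- data.frame(woman_id = c("a", "a", "b"), x = c(1, 2, 3),
                  y = c(1, 2, 2))
  fit <- panel_lm(y ~ x, d, estimator = "pooled")
  expect_equal(unname(coef(fit)), c(2 / 3, 0.5), tolerance = 1e-12)
  # exact line
  d2 <- data.frame(woman_id = rep("a", 4), x = 1:4, y = 3 + 2 * (1:4))
  expect_equal(unname(coef(panel_lm(y ~ x, d2, estimator = "pooled"))),
               c(3, 2), tolerance = 1e-12)
  # pooled residuals orthogonal to the design
  r <- residuals(fit)
  expect_equal(sum(r), 0, tolerance = 1e-10)
  expect_equal(sum(r * d$x), 0, tolerance = 1e-10)
  # constant covariate is singular
  d3 <- data.frame(woman_id = c("a", "a", "b"), x = c(2, 2, 2), y = 1:3)
  expect_error(panel_lm(y ~ x, d3, estimator = "pooled"), "singular")
})

test_that("LSDV equals least squares on the dummy-expanded design", {
  set.seed(12)
  for (rep in 1:5) {
    d <- data.frame(woman_id = rep(letters[1:3], each = 4),
                    x = rnorm(12, 30, 3), y = rnorm(12, 14, 2))
    fit <- panel_lm(y ~ x, d, estimator = "lsdv")
    oracle <- lm(y ~ 0 + woman_id + x, data = d)
    expect_equal(unname(coef(fit)[2]), unname(coef(oracle)["x"]),
                 tolerance = 1e-8)
    expect_equal(unname(fit$woman_effects[c("a", "b", "c")]),
                 unname(coef(oracle)[paste0("woman_id", c("a", "b", "c"))]),
                 tolerance = 1e-8)
  }
})

test_that("LSDV recovers exact per-woman lines and ignores level shifts", {
  d <- data.frame(woman_id = rep(c("1", "2", "3"), each = 3),
                  x = c(1, 2, 3, 2, 4, 6, 1, 3, 5))
  d$y <- 5 * as.integer(d$woman_id) + 2 * d$x
  fit <- panel_lm(y ~ x, d, estimator = "lsdv")
  expect_equal(unname(coef(fit)[2]), 2, tolerance = 1e-12)
  expect_equal(unname(fit$woman_effects), c(5, 10, 15), tolerance = 1e-12)
  # within-transform invariance: per-woman shifts leave the slope alone
  shift <- c("1" = 4, "2" = -2, "3" = 100)
  d2 <- d
  d2$y <- d$y + shift[d$woman_id]
  expect_equal(coef(panel_lm(y ~ x, d2, estimator = "lsdv"))[2],
               coef(fit)[2], tolerance = 1e-12)
  # no within-woman x variation anywhere -> singular
  d3 <- data.frame(woman_id = rep(c("a", "b"), each = 2),
                   x = c(1, 1, 2, 2), y = rnorm(4))
  expect_error(panel_lm(y ~ x, d3, estimator = "lsdv"), "within-woman")
})

test_that("variance components recover generative variances", {
  # perfect fit -> all components zero
  d <- data.frame(woman_id = rep(c("a", "b"), each = 3),
                  x = c(1, 2, 3, 4, 5, 6))
  d$y <- 1 + 2 * d$x
  vc0 <- variance_components(panel_lm(y ~ x, d, estimator = "pooled"))
  expect_equal(vc0$xi_mu, 0, tolerance = 1e-20)
  expect_equal(vc0$xi_alpha, 0, tolerance = 1e-20)
  expect_equal(vc0$xi_eps, 0, tolerance = 1e-20)

  p <- recovery_panel(1, 0.5, sigma_alpha = 1, sigma_eps = 1,
                      n_women = 800, T = 6, seed = 77)
  vc <- variance_components(panel_lm(y ~ x, p, estimator = "pooled"))
  expect_equal(vc$xi_alpha, 1, tolerance = 0.15)
  expect_equal(vc$xi_eps, 1, tolerance = 0.1)
  expect_equal(vc$xi_mu, vc$xi_alpha + vc$xi_eps, tolerance = 1e-12)

  p0 <- recovery_panel(1, 0.5, sigma_alpha = 0, sigma_eps = 1,
                       n_women = 800, T = 6, seed = 78)
  vc0b <- variance_components(panel_lm(y ~ x, p0, estimator = "pooled"))
  expect_lt(abs(vc0b$xi_alpha), 0.05)
})

test_that("GLS matches explicit Omega-weighted normal equations", {
  set.seed(55)
  for (rep in 1:5) {
    p <- recovery_panel(2, 0.3, sigma_alpha = 1, sigma_eps = 1.5,
                        n_women = 6, T = 3)
    p <- p[-c(2, 8), ]  # unbalance the panel
    fit <- panel_lm(y ~ x, p, estimator = "gls")
    vc <- fit$components
    g <- factor(p$woman_id)
    O <- matrix(0, nrow(p), nrow(p))
    for (w in levels(g)) {
      i <- which(g == w)
      O[i, i] <- vc$xi_alpha
    }
    diag(O) <- diag(O) + vc$xi_eps
    X <- cbind(1, p$x)
    oracle <- solve(t(X) %*% solve(O) %*% X, t(X) %*% solve(O) %*% p$y)
    expect_equal(unname(coef(fit)), as.numeric(oracle), tolerance = 1e-8)
    # residuals orthogonal to regressors in the Omega-inverse metric
    r <- p$y - X %*% oracle
    expect_lt(max(abs(t(X) %*% solve(O) %*% r)), 1e-8)
  }
  # 2 women x 2 observations toy instance
  toy <- data.frame(woman_id = c("a", "a", "b", "b"),
                    x = c(25, 30, 28, 35), y = c(11, 14, 15, 18))
  fit <- panel_lm(y ~ x, toy, estimator = "gls",
                  components = list(xi_alpha = 0.8, xi_eps = 1.5))
  O <- rbind(c(2.3, 0.8, 0, 0), c(0.8, 2.3, 0, 0),
             c(0, 0, 2.3, 0.8), c(0, 0, 0.8, 2.3))
  X <- cbind(1, toy$x)
  oracle <- solve(t(X) %*% solve(O) %*% X, t(X) %*% solve(O) %*% toy$y)
  expect_equal(unname(coef(fit)), as.numeric(oracle), tolerance = 1e-8)
})

test_that("GLS interpolates between pooled OLS and the within estimator", {
  p <- recovery_panel(1, 0.4, sigma_alpha = 1, sigma_eps = 1,
                      n_women = 40, T = 5, seed = 13)
  pooled <- panel_lm(y ~ x, p, estimator = "pooled")
  lsdv <- panel_lm(y ~ x, p, estimator = "lsdv")
  # xi_alpha = 0: Omega proportional to identity, GLS == pooled OLS
  g0 <- panel_lm(y ~ x, p, estimator = "gls",
                 components = list(xi_alpha = 0, xi_eps = 1))
  expect_equal(coef(g0), coef(pooled), tolerance = 1e-10)
  # xi_alpha / xi_eps -> infinity: GLS slope -> within slope
  ginf <- panel_lm(y ~ x, p, estimator = "gls",
                   components = list(xi_alpha = 1e10, xi_eps = 1))
  expect_equal(unname(coef(ginf)[2]), unname(coef(lsdv)[2]),
               tolerance = 1e-4)
  # degenerate covariance is refused
  expect_error(panel_lm(y ~ x, p, estimator = "gls",
                        components = list(xi_alpha = 1, xi_eps = 0)),
               "degenerate")
})

test_that("GLS recovers generative coefficients on random-effect panels", {
  set.seed(2024)
  est <- t(sapply(1:40, function(i) {
    p <- recovery_panel(0.501, -0.088, sigma_alpha = 0.5, sigma_eps = 1,
                        n_women = 200, T = 8)
    coef(panel_lm(y ~ x, p, estimator = "gls"))
  }))
  m <- colMeans(est)
  se <- apply(est, 2, sd) / sqrt(nrow(est))
  expect_lt(abs(m[1] - 0.501), 3 * se[1] + 1e-12)
  expect_lt(abs(m[2] + 0.088), 3 * se[2] + 1e-12)
})

test_that("Hausman statistic, p-value and both decision rules", {
  p <- recovery_panel(1, 0.3, sigma_alpha = 0.7, sigma_eps = 1,
                      n_women = 60, T = 4, seed = 3)
  fx <- panel_lm(y ~ x, p, estimator = "lsdv")
  rd <- panel_lm(y ~ x, p, estimator = "gls")
  h <- hausman_test(fx, rd)
  expect_equal(h$statistic, (coef(rd)[[2]] - coef(fx)[[2]])^2,
               tolerance = 1e-12)
  expect_gte(h$statistic, 0)
  expect_true(h$p.value >= 0 && h$p.value <= 1)

  # equal slopes -> H = 0, p = 1
  rd0 <- rd
  rd0$coefficients[2] <- fx$coefficients[2]
  h0 <- hausman_test(fx, rd0)
  expect_equal(h0$statistic, 0)
  expect_equal(h0$p.value, 1)

  # chi-squared(1) upper-tail oracle: H at the 95th percentile gives p = .05
  rd05 <- rd
  rd05$coefficients[2] <- fx$coefficients[2] + sqrt(qchisq(0.95, df = 1))
  h05 <- hausman_test(fx, rd05)
  expect_equal(h05$p.value, 0.05, tolerance = 1e-10)
  # published rule rejects the random-effect model on LARGE p; probe just
  # inside the rejection region to keep clear of the 0.05 boundary
  rd04 <- rd
  rd04$coefficients[2] <- fx$coefficients[2] + sqrt(qchisq(0.96, df = 1))
  expect_equal(hausman_test(fx, rd04)$favored, "random")
  expect_equal(hausman_test(fx, rd04, rule = "standard")$favored, "fixed")
  expect_equal(h0$favored, "fixed")
  expect_equal(hausman_test(fx, rd0, rule = "standard")$favored, "random")
})

test_that("under the random-effect model the two slopes rarely disagree", {
  set.seed(61)
  H <- replicate(30, {
    p <- recovery_panel(1, 0.3, sigma_alpha = 0.5, sigma_eps = 1,
                        n_women = 150, T = 6)
    fx <- panel_lm(y ~ x, p, estimator = "lsdv")
    rd <- panel_lm(y ~ x, p, estimator = "gls")
    hausman_test(fx, rd)$statistic
  })
  expect_gt(mean(H < 0.01), 0.8)
})

test_that("panel_lm methods behave (predict, simulate, summary, print)", {
  p <- recovery_panel(2, 0.5, sigma_alpha = 1, sigma_eps = 1,
                      n_women = 50, T = 4, seed = 8)
  fit <- panel_lm(y ~ x, p, estimator = "gls")
  expect_equal(predict(fit), fitted(fit))
  nd <- data.frame(x = c(25, 30))
  expect_equal(predict(fit, nd),
               unname(coef(fit)[1] + coef(fit)[2] * c(25, 30)))
  expect_error(predict(fit, data.frame(z = 1)), "must contain")
  lf <- panel_lm(y ~ x, p, estimator = "lsdv")
  nd2 <- data.frame(x = c(25, 30), woman_id = c("W00001", "zzz"))
  pr <- predict(lf, nd2, use_woman_effects = TRUE)
  expect_equal(pr[1],
               unname(lf$woman_effects["W00001"] + coef(lf)[2] * 25))
  sims <- simulate(fit, nsim = 3, seed = 1)
  expect_equal(dim(sims), c(nrow(p), 3L))
  # simulated responses re-fit near the generating slope (the intercept is
  # an extrapolation far outside the covariate range, so it is noisier)
  p2 <- p
  p2$y <- sims$sim_1
  refit <- panel_lm(y ~ x, p2, estimator = "gls")
  expect_lt(abs(coef(refit)[[2]] - coef(fit)[[2]]), 0.2)
  s <- summary(fit)
  expect_true(all(c("Estimate", "Std. Error") %in%
                  colnames(s$coefficients)))
  expect_output(print(fit), "gls")
  expect_output(print(s), "Variance components")
  expect_output(print(hausman_test(panel_lm(y ~ x, p, estimator = "lsdv"),
                                   fit)), "Hausman")
})
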