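# ovucal

Calendar-based ovulation prediction from self-tracked menstrual cycle logs.

Millions of women log menstruation onsets (and occasionally ovulation test
results) in cycle-tracking apps. `ovucal` turns such event logs into
per-cycle phase lengths and asks how well the day of the next ovulation can
be predicted from *calendar data alone* — no temperature, no hormone
assays. It is aimed at biostatisticians and digital-health researchers who
work with longitudinal cycle data.

## The model

A cycle of length *c* decomposes as *c = f + l + 1*: follicular phase *f*
(onset to ovulation), the ovulation day, luteal phase *l*. The predictor
available before a cycle starts is the trailing mean cycle length
*c\*(k)*, the mean of the woman's previous *k* cycles. Three rules predict
ovulation as a number of days after the last onset:

| method | prediction μ |
|---|---|
| Ogino | ⌊c\*⌋ − 15 (fixed 14-day luteal phase) |
| HCL (half cycle length) | ⌊c\*/2⌋ |
| Optimized | ⌊α + β·c\*⌋, with (α, β) fitted on (c\*, f) panels |

The optimized line is fitted with `panel_lm()`, which implements pooled
OLS, the fixed-effect within estimator (LSDV), and random-effect GLS under
a compound-symmetric residual covariance (woman-level variance ξ_α,
within-woman variance ξ_ε, estimated by moments from pooled residuals),
plus the unnormalized Hausman statistic H = (β_gls − β_lsdv)² for choosing
between the fixed- and random-effect views. Predictions are scored per
integer mean-cycle-length bin as the fraction of cycles with |μ − f| ≤ e
for allowable errors e = 0, 1, 2 days.

Because app cohorts are proprietary, the package includes a seeded
generator (`generate_population()`, calibrated by `table1_preset()` to a
published reference cohort summary shipped under `inst/extdata/`) so the
entire pipeline is reproducible from nothing.

## Worked example

```r
library(ovucal)

cfg <- table1_preset(n_women = 800, seed = 20)  # cohort-calibrated preset
ev  <- generate_population(cfg)                 # dated event log
cyc <- derive_cycles(ev)                        # screen 20-45 d, attach ovulation

p   <- panel_for_k(cyc, k = 1)                  # x = c*(1), y = f
fit <- panel_lm(y ~ x, p, id = "woman_id", estimator = "gls")
summary(fit)
#> Panel linear model, estimator = gls
#> Observations: 420  Women: 317
#>
#>             Estimate Std. Error t value  Pr(>|t|)
#> (Intercept) 2.911378   1.038440  2.8036  0.005289 **
#> x           0.389693   0.037048 10.5187 < 2.2e-16 ***
#>
#> Variance components: xi_mu = 6.969, xi_alpha = 1.398, xi_eps = 5.572

hausman_test(panel_lm(y ~ x, p, id = "woman_id", estimator = "lsdv"), fit)
#> Hausman specification test (unnormalized)
#>   H = (beta_gls - beta_lsdv)^2 = 0.205389, p = 0.6504 [chisq(1)]
#>   rule = as_published; favored model: fixed effects

opt <- fit_optimized(cyc, k = 1)
evaluate_accuracy(cyc, errors = 0:2, k_range = 1)$mean
#>   method e k mean_accuracy
#> 1    hcl 0 1    0.19099583
#> 2    hcl 1 1    0.51273031
#> 3    hcl 2 1    0.66349652
#> 4  ogino 0 1    0.08420763
#> 5  ogino 1 1    0.24716329
#> 6  ogino 2 1    0.42589185
#> 7    opt 0 1    0.14874599
#> 8    opt 1 1    0.46262652
#> 9    opt 2 1    0.63145825

predict_ovulation_date("2024-03-01", "opt", c_star = 33, fit = opt)
#> [1] "2024-03-16"
```

Reading the output: the GLS slope ~0.39 says each extra day of mean cycle
length moves ovulation ~0.39 days later (attenuated below the ~0.7
between-woman trend because a short trailing mean is a noisy measure of a
woman's level); the tiny Hausman H says the fixed- and random-effect slopes
agree. In the accuracy table the optimized method beats Ogino at every
allowable error, with its advantage concentrated in women whose mean cycle
is far from 28–31 days — for a 33-day mean it predicts ovulation on day 15,
where Ogino would say day 18. The full `simulate → derive → fit → evaluate
→ report` chain, with CSV/JSON artifacts, is `run_pipeline(pipeline_config(...))`.

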