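---
title: "Modelling menstrual cycle phases and predicting ovulation from calendar data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling menstrual cycle phases and predicting ovulation from calendar data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ovucal)
```

## The problem

Calendar-based family-planning methods predict the day of the next ovulation
from nothing but the timing of past menstruation onsets. A woman's cycle of
length $c$ splits into a follicular phase of length $f$ (onset to ovulation),
the ovulation day itself, and a luteal phase of length $l$, so that

$$c = f + l + 1 .$$

The classical Ogino rule assumes the luteal phase is fixed at 14 days and
predicts ovulation $\lfloor c^\* \rfloor - 15$ days after the last onset,
where $c^\*$ is the woman's mean cycle length; the half-cycle-length (HCL)
rule predicts $\lfloor c^\*/2 \rfloor$. Large self-tracked datasets make a
third option possible: *fit* the linear relationship between follicular
phase length and mean cycle length across many women and use the fitted
line, floored to whole days, as the predictor,
$\mu_{\mathrm{OPT}} = \lfloor \alpha + \beta c^\* \rfloor$. This package
implements the full pipeline: deriving phase lengths from event logs,
fitting the line with panel estimators, and scoring all three predictors at
allowable errors of 0, 1 and 2 days.

## From event logs to phase lengths

The raw data are dated events per woman: menstruation onsets, and ovulation
records labelled by their basis (clinical diagnosis, ovulation test kit, or
other). Cycles are indexed by recency — cycle $j = 1$ is the most recent —
and cycle $j$ spans onset $j+1$ to onset $j$. Derivation applies three
rules, in this order:

1. **Screening.** Cycles shorter than 20 or longer than 45 days are removed
   as likely logging errors (missed onsets produce apparent 60-day cycles).
   Both bounds are inclusive on the *kept* side: 20- and 45-day cycles stay.
2. **Basis filter.** Only clinical and test-kit ovulation records are
   trusted by default; "other" records are ignored.
3. **Attachment.** A trusted record dated strictly between a cycle's onsets
   sets $f$ (days from the starting onset) and $l = c - f - 1$ (the day
   after ovulation through the day before the next onset). A record dated
   exactly on an onset is contradictory input and is discarded with a
   warning. If two trusted records fall in one cycle the annotation is
   dropped (default) or the earliest kept (`multiple = "earliest"`); logs
   rarely contain such conflicts and no principled resolution exists.

All dates are handled at day resolution — the start day of menstruation is
a user's subjective report and sub-day precision would be spurious.

The predictor used everywhere downstream is the trailing mean
$c^\*_{j}(k)$: the mean of the $k$ cycles immediately preceding cycle $j$,
computable only when all $k$ of them exist *after* screening (a screened-out
cycle breaks the window; with $k = 1$ the trailing mean is just the previous
cycle's length). Whether the basis filter should run before or after
screening is immaterial to any quantity defined here, since attachment only
annotates cycles that survived screening; the pipeline screens first.

## Panel estimators

Phase length against trailing mean cycle length is a panel regression:
women contribute unequal numbers of cycles and have their own levels. For
$y_{it} = \alpha + \beta x_{it} + \mu_{it}$, `panel_lm()` implements:

* **Pooled OLS**, ignoring the grouping.
* **LSDV / within estimator** (fixed effects): per-woman intercepts
  $\alpha_i = \bar y_i - \beta\,\bar x_i$, slope from within-woman
  variation,
  $\beta = \sum_i \sum_t (x_{it}-\bar x_i)(y_{it}-\bar y_i) \big/
  \sum_i \sum_t (x_{it}-\bar x_i)^2$.
* **Random-effect GLS** under compound symmetry: the residual
  $\mu_{it} = a_i + \varepsilon_{it}$ has within-woman covariance
  $\xi_\alpha$ and diagonal $\xi_\alpha + \xi_\varepsilon$. Moment
  estimates come from pooled residuals with $p = 2$ parameters and, for
  unbalanced panels, $\sum_i T_i$ and $\sum_i T_i(T_i-1)/2$ in the
  denominators:
  $\hat\xi_\mu = \sum \mu_{it}^2 / (\sum T_i - p)$,
  $\hat\xi_\alpha = \sum_i \sum_{t<s} \mu_{it}\mu_{is} /
  (\sum_i T_i(T_i-1)/2 - p)$, and
  $\hat\xi_\varepsilon = \hat\xi_\mu - \hat\xi_\alpha$. Negative
  $\hat\xi_\alpha$ (possible in small samples) is clamped to zero with a
  warning. The GLS solution is computed by quasi-demeaning with
  $\theta_i = 1 - \sqrt{\xi_\varepsilon / (\xi_\varepsilon + T_i
  \xi_\alpha)}$, which is algebraically the block inverse of the
  compound-symmetric covariance; the tests verify this against explicitly
  solved $\Omega^{-1}$-weighted normal equations, and the two limits
  ($\xi_\alpha = 0 \Rightarrow$ pooled OLS;
  $\xi_\alpha/\xi_\varepsilon \to \infty \Rightarrow$ the within slope).

The **Hausman test** is implemented exactly in its published form for this
analysis: $H = (\beta_{\mathrm{gls}} - \beta_{\mathrm{lsdv}})^2$, referred
to $\chi^2(1)$, with *no* variance normalization. Its default decision rule
("reject the random-effect model when $p > .05$") likewise follows the
published wording even though it inverts conventional practice — the
conventional direction is available as `rule = "standard"`, and the two
rules disagree on every dataset, so the choice is documented rather than
silently made.

A deliberate scientific caveat: with $x = c^\*(k)$, the within-woman
variation of $x$ is mostly noise around the woman's level, so the within
slope is attenuated towards zero and GLS — which blends within and between
information — yields a flatter line than the between-woman trend. The slope
therefore *rises* with $k$ as the trailing mean becomes less noisy. This is
visible in `per_k_fits()` output and is a property of the estimand, not an
implementation artifact; the estimator behind the optimized predictor is
configurable (`estimator = "pooled"` uses the conditional-mean line, which
is the best predictor of $f$ given $c^\*$ in mean-square terms).

## The synthetic cohort generator

The real data behind analyses of this kind are proprietary app logs, so the
package ships a seeded generator, `generate_population()`, that reproduces
the *structure* every downstream stage relies on: women with variable-length
onset series ($T_i$ uniform on 2–15, so analyses at $k = 1, \dots, 8$ are
all populated), integer cycle lengths from a woman-level random intercept
model $c_{it} = \mathrm{round}(\mu_0 + a_i + e_{it})$ clamped to 20–45,
follicular lengths linear in the realized cycle length
$f_{it} = \mathrm{round}(\gamma_0 + \gamma_1 c_{it} + u_i + v_{it})$
clamped to $[1, c-1]$, luteal lengths $l = c - f - 1$ by construction, and
ovulation *observed* in only a small fraction of cycles with basis labels
drawn from fixed proportions (0.31 clinical / 0.54 test kit / 0.15 other).
Gaussian draws are rounded then clamped — clamping rather than rejection
keeps cycle counts exactly as configured, and at the default spreads the
clamp touches well under 1% of draws.

`table1_preset()` calibrates the defaults to the shipped reference cohort
summary (`cohort_phase_summary()`, 7043 women, 12,731 ovulation-dated of
135,666 logged cycles):

* $\mu_0 = 28$ d — the summary's modal cycle length;
* total cycle SD 3.50 d — the count-weighted SD of the summary rows — split
  into between/within SDs of 2.57/2.37 d via an intra-class correlation of
  0.54, the reported lag-1 correlation between consecutive cycle lengths;
* $(\gamma_0, \gamma_1) \approx (-6.67, 0.726)$ — the unweighted OLS line
  through the summary's per-row mean follicular lengths;
* $\sigma_u = 1.0$, $\sigma_v = 1.2$ d — chosen once as a compromise: the
  summary's within-row 95% ranges suggest a conditional SD near 2 d, while
  the reported correlations between trailing mean and phase lengths imply
  one nearer 1 d; the middle ground keeps both qualitative patterns (a
  strong follicular and a weak luteal correlation with $c^\*$);
* ovulation-logging probability $12731/135666 \approx 0.094$.

What the generator does **not** emulate: cycle-length autocorrelation
beyond the random intercept, anovulatory cycles, age effects, digit
heaping, or the right skew of real cycle-length distributions (the
generator is symmetric around $\mu_0$, so its mean is 28 rather than the
cohort's 29.8 — mode was preferred over mean because the accuracy curves
are read per integer bin). Passing tests therefore demonstrate correctness
of the *pipeline and estimators* under a plausibly structured cohort, not
fidelity of any particular real population.

`recovery_panel()` bypasses the event-log layer entirely and draws
$(x, y)$ panels straight from the random-effect model; it is the
ground truth for estimator-recovery checks (500 women × 8 cycles × 200
replicates in the shipped acceptance script, a size chosen so the full
recovery run completes in seconds while the Monte-Carlo standard error on
each coefficient is below 0.01).

## Evaluating the calendar methods

`evaluate_accuracy()` scores each method on the ovulation-dated cycles with
a computable $c^\*(k)$: a prediction is correct when
$|\mu - f| \le e$ for allowable error $e \in \{0, 1, 2\}$ days. Results
are binned by nearest-integer rounding of $c^\*$ (the reference tables
report integer bins; the rounding rule itself is a choice, and rounding —
rather than flooring — keeps bins centred on their labels). Bin-level
accuracies are summarized across bins with an *unweighted* mean by default,
treating each mean-cycle-length bin as one unit; `pooled = TRUE` weights by
cycle counts instead. The optimized predictor is fitted in-sample on the
full dataset by default, mirroring how such rules are derived from a whole
cohort; because in-sample evaluation flatters the optimized method, a
woman-level hold-out (`fit_optimized(..., holdout = )`) restricts
evaluation to women the fit never saw.

Numerical conventions, in one place: all bracketed predictions use
`floor()` (stated for the Ogino rule; applied to HCL and the optimized
line for consistency); optimized predictions below 1 day are flagged
invalid (`NA`) and count as incorrect; empty bins are omitted; Pearson
p-values use the exact $t$ transform on $n - 2$ degrees of freedom; the
screened band, basis filter, and every estimator tolerance are exercised
in the test suite against independent oracles (explicit dummy-variable
regression, explicit $\Omega^{-1}$ normal equations, brute-force window
enumeration).

On preset cohorts the package reproduces the qualitative findings the
method comparison is known for: the follicular correlation with $c^\*$ far
exceeds the luteal one; the optimized method matches Ogino near 28–31-day
means (where a fixed 14-day luteal phase is approximately right) and beats
it increasingly far from that band; and its mean accuracy across bins is at
least Ogino's at every allowable error. The shipped acceptance script and
`test-acceptance.R` compute exactly these quantities at run time.

## Known limitations

* The optimized predictor is a single line per $k$; no woman-specific
  shrinkage or biomarker input (temperature, LH tests) is modelled.
* Variance components are method-of-moments, not REML; standard errors are
  model-based, with no robust/clustered option.
* One covariate per model, by design — the published estimators this
  package implements are simple regressions, and `panel_lm()` enforces
  that.
* The record-depth profile of a real cohort (57% of ovulation-dated cycles
  with 8+ past records in the reference tables) is flatter than the uniform
  $T_i$ default produces (~20%); analyses conditional on $k$ are unaffected,
  but cross-$k$ sample-size ratios are not calibrated.
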