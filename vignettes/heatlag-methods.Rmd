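---
title: "Modelling temperature–mortality relationships with heatlag"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling temperature–mortality relationships with heatlag}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`heatlag` estimates short-term effects of ambient temperature on daily
death counts with a negative binomial distributed lag non-linear model
(DLNM).  Daily counts $Y_t$ are taken as

$$Y_t \sim \mathrm{NB}(\mu_t, \theta), \qquad
\log \mu_t = \alpha + \mathbf{w}_t^{\mathsf T}\boldsymbol\beta
 + \gamma_{\mathrm{dow}(t)} + s_{\mathrm{time}}(t)
 + s_h(\mathrm{humidity}_t) + s_d(\mathrm{dewpoint}_t),$$

where $\mathbf{w}_t$ is the row of a *cross-basis*: the tensor product of
a basis over the temperature axis and a basis over the lag axis,

$$\mathbf w_t[(j,k)] \;=\; \sum_{l=0}^{L} V_j(x_{t-l})\, B_k(l),$$

with $V$ a natural cubic spline (NCS) in temperature and $B$ an NCS in
lag days augmented with a constant-in-lag column.  The NB2
parameterisation (variance $\mu + \mu^2/\theta$) absorbs the
overdispersion that daily death counts of a small city invariably show;
$\theta$ is estimated jointly with the coefficients by maximum
likelihood (via `MASS::glm.nb`), and the reported AIC counts it:
$\mathrm{AIC} = -2\ell + 2(p + 1)$.

Seasonality and long-term trend are controlled by an NCS in the day
index with a *per-year* degrees-of-freedom budget; the total df is
`round(time_df_per_year * n_years)`, so "5 df per year" over five years
yields a 25-column block.  Day-of-week enters as six indicators against
a Monday reference (the choice of reference is effect-invariant), and
average relative humidity and dew point temperature are given 3-df NCS
smooths by default.

All effect summaries are linear contrasts of the cross-basis block. For
a temperature `at` versus a reference `ref`, cumulated over lags
$l_0..l_1$, the log relative risk is $c^{\mathsf T}\beta$ with

$$c[(j,k)] = \big(V_j(\mathrm{at}) - V_j(\mathrm{ref})\big)
             \sum_{l=l_0}^{l_1} B_k(l),$$

and the 95% CI is the Wald/delta interval
$\exp(c^{\mathsf T}\hat\beta \pm 1.96\,\sqrt{c^{\mathsf T}\hat V c})$
using the cross-basis block of the coefficient covariance.  A degenerate
cross-basis (linear temperature term, one indicator per lag) makes the
familiar closed form visible: the cumulative lag 0–2 effect of a
6.1 °C contrast is exactly $\exp((\beta_0+\beta_1+\beta_2)\times 6.1)$.

## Parameters that matter

* `max_lag` (days, default 28): the window over which temperature can
  act.  Heat effects concentrate at short lags, cold effects at long
  lags, so summaries default to lag 0–2 for heat and 0–28 for cold.
* `var_df` (default 4) and `lag_df` (default 5): the df of the
  temperature and lag bases.  The lag df *includes* the constant-in-lag
  column; under this convention a 1-df lag basis reduces the model to a
  moving-sum (cumulative) term, which keeps the degenerate cases exactly
  testable.  The alternative convention is available via
  `lag_intercept = FALSE`.
* Knot placement: temperature, time and confounder knots sit at equally
  spaced quantiles of the observed values (boundary at the range); lag
  knots sit at equally spaced values on the raw lag scale.  Both are
  overridable with an explicit `knot_spec`, for users who prefer other
  conventions (e.g. log-scale lag knots).
* `time_df_per_year` (default 5): seasonality/trend control.
* Percentile contrasts (defaults 1 / 50 / 99): computed from the
  complete-case temperature series by linear interpolation between order
  statistics (R type-7), the package-wide quantile rule.

The `hue2016()` preset bundles the configuration of a published
five-year tropical-monsoon-city analysis (average temperature, 4×5-df
NCS–NCS cross-basis, max lag 28, 5 df/year time spline, 3-df humidity
and dew point smooths, day-of-week indicators) so that the final model
family can be applied without re-running selection.

## Model selection

`select_model()` implements an objective-oriented AIC search over four
components: (1) time df per year, (2) temperature indicator (maximum,
average, minimum), (3) temperature-dimension df, (4) lag-dimension df.
The sequential strategy fixes the components in that order, holding
not-yet-selected ones at the midpoint of their candidate range (and
average temperature); the exhaustive strategy fits the full Cartesian
grid.  Ties break toward smaller df, then toward average temperature.
Every attempted fit is recorded in the trace with its AIC (or failure
reason), and the chosen model's AIC equals the minimum of its step by
construction.  Sequential search restricts the exhaustive one, so its
chosen AIC can never beat the exhaustive minimum — a relation the test
suite asserts.

## The synthetic-data generator

Because line-listed mortality registers are rarely shareable, every
stage of the package is exercised against a generator that emulates the
*structure* of a humid tropical city's data:

* **Temperature**: mean 25.7 °C, marginal SD 4.1 °C, an annual sinusoid
  (default amplitude 4.8 °C, peak near the summer solstice) plus AR(1)
  noise with lag-1 correlation 0.7.  The innovation variance is derived
  from the identity $\mathrm{Var} = A^2/2 + \sigma^2_{\mathrm{AR}}$, so
  the implied marginal SD equals the target exactly.  Amplitude and
  persistence are pragmatic choices giving a realistic-looking seasonal
  cycle and multi-day weather spells; the generator makes no claim of
  climate realism (no monsoon asymmetry, no climate change trend).
* **Other weather**: daily maximum/minimum offset about +4.2/−4.0 °C
  from the average; dew point a positive depression (mean 3.6 °C) below
  the average; relative humidity from the depression via the Magnus
  approximation, clipped to (0, 100].  Humidity and dew point carry no
  effect on simulated mortality — they exist so the confounder smooths
  of the model have realistic inputs.
* **Counts**: $\log\mu_t$ = log(3.4) + cumulative surface effect +
  day-of-week (+5% weekends by default) + optional trend;
  $Y_t \sim \mathrm{NB2}(\mu_t, \theta{=}8)$.  $\theta = 8$ reproduces
  the variance/mean ratio of roughly 1.4 seen in overdispersed daily
  counts around this baseline.  Stratified counts (cause, sex, age) come
  from multinomial thinning with fixed proportions (35.6% cardiovascular,
  17.3% cancer, 2.9% respiratory, 5.9% external, 53.5% male, 65.5%
  aged ≥ 65), so strata partition the all-cause count by construction.
* **True surfaces**: closed-form exposure–lag–response functions
  $f(x, l)$ anchored at 15.8 / 26.3 / 32.4 °C (the 1st/50th/99th
  percentile anchors), with $f(\mathrm{ref}, l) = 0$: `J` (heat only,
  quadratic ramp, exponentially decaying lag weights), `L` (cold only,
  delayed bell-shaped weights), `U` (both), `linear`, `null`, and
  `displacement` (acute heat excess on lags 0–2 with a compensating
  deficit on lags 3–10).  `true_cumulative_rr()` evaluates any contrast
  exactly and is the oracle of the recovery experiments.
  `crossbasis_surface()` builds surfaces that lie *exactly* in a given
  tensor-spline family, for selection-recovery experiments where "the
  true df" is well defined.

### Lag resolution and the default heat profile

A smooth lag basis cannot represent arbitrarily spiky lag profiles: with
knots at 7/14/21 days, a 5-df NCS in lag resolves features at roughly
weekly scale.  Exponential heat profiles with an e-folding time below
about 3 days fall under that resolution and are recovered with a
systematic attenuation of the acute (lag 0–2) cumulative effect — a
projection bias that no amount of data removes.  The canonical `J`
surface therefore uses a 4-day e-folding (about 85% of the effect within
the first week), which the preset basis resolves essentially without
bias, and sharper profiles remain available through `hot_lag_decay` for
users who want to study the attenuation itself.  The displacement
surface intentionally keeps its spiky acute component: the corresponding
experiment asks only for the *sign pattern* (excess at lag 0, deficit
somewhere in lags 3–10), which survives smoothing.

## Validation experiments and their scale

The test suite and `scripts/acceptance.R` re-run the same battery of
experiments; the sizes below are the package's chosen design:

* oracle equivalences (truncated-power spline basis; brute-force
  cross-basis; closed-form contrast) on small fixed inputs;
* delta-method CIs against a 100 000-draw multivariate-normal parametric
  bootstrap of the cross-basis coefficients;
* coverage: 50 five-year replicates from the `J` surface, preset fit,
  checking the true acute heat RR falls in the 95% CI;
* displacement detection and null-surface false-positive rates, each on
  50 five-year replicates (the null runs go through the full sequential
  AIC selection before summarisation);
* selection sanity: 50 replicates from a 4-df-temperature × 3-df-lag
  spline surface, exhaustive search over `var_df` 2–6 × `lag_df` 2–4.

Passing these shows the estimation machinery is correct *under the
generator's assumptions*: NB2 counts, a true surface in (or near) the
model family, stationary seasonal weather, complete records.  It does
not certify performance on real data with registration artefacts,
missing weather, influenza epidemics, or air-pollution confounding —
none of which the generator emulates.

## Numerical and design choices

* Rows whose lag window reaches before the series start or spans a gap
  are *masked*, never imputed; gaps in the calendar are padded as NA
  rows by `daily_series()` so lag alignment cannot silently corrupt.
* The basis parameterisation is free (whatever `splines::ns` returns);
  all reported quantities — fitted means, AIC, RRs — are invariant to
  affine reparameterisation, and the tests assert exactly that
  invariance (e.g. shifting temperatures and knots by +50 °C changes no
  output).
* Extrapolation beyond the boundary knots is linear (the natural
  condition) rather than an error, because percentile contrasts can sit
  slightly outside the complete-case range.
* Cumulative curves across nested windows are, by default, re-fitted
  with `max_lag` equal to the window end (`curve_refit = TRUE` in
  `study_config()`), since the lag-basis df interacts with the maximum
  lag; re-summarising the single full-lag fit is available as the
  alternative.
* "5 df per year" is interpreted as a *total* df of
  `round(5 × n_years)` on the day index, not as knots per calendar
  year; the per-year interpretation can be emulated with an explicit
  time df.
* Degenerate inputs fail loudly: all-zero responses, non-integer or
  negative counts, non-finite basis inputs, lag windows outside range,
  and non-PSD covariance blocks are errors, not warnings.

## Known limitations

* Inference after selection is approximate: the selection step is not
  accounted for in the CIs, and with ~60 parameters on ~1800 days the
  Wald intervals are slightly anti-conservative even without selection.
  The null-surface experiment quantifies the joint hot-or-cold
  false-positive rate; across seed batches it ranges from about the
  nominal two-test level (~10%) to roughly twice that, the excess being
  the price of selecting the basis dimensions by AIC on the same data
  before reading the intervals.  Users who need strict error control
  should fix the model family a priori (e.g. the preset) or validate on
  held-out periods.
* Smooth lag bases attenuate sub-weekly lag structure (see above).
* The quantile rule, day-of-week reference, and AIC dispersion-counting
  conventions are fixed package-wide; they are effect-invariant or
  selection-invariant respectively, but differ from some other software.
* No offset/population term: rates are modelled as counts under a
  constant population, appropriate for short series only.
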