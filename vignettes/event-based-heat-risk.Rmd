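---
title: "Event-based modelling of heatwave excess mortality"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Event-based modelling of heatwave excess mortality}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(heatmort)
```

## The model

Sustained heat kills: during and shortly after a heatwave, daily all-cause
mortality rises above its background level. `heatmort` implements an
event-based formulation of that relationship. The daily all-cause mortality
rate $p$ (carried throughout in units of $10^{-6}\,\mathrm{day}^{-1}$) is
decomposed into a base rate $p_0$ and a heat-attributable excess $p_h$:

$$p = \frac{N_\mathrm{death}}{N} = p_0 + p_h, \qquad p_h = M\,\alpha .$$

A *heatwave event* is a maximal run of at least three consecutive days on
which the daily maximum of a temperature indicator $T_x$ strictly exceeds a
threshold $T_{th}$. The $i$-th event, starting on day $d_i$ with duration
$D_i$, has a log-scale magnitude

$$M_i = \log_{10}\Bigl[1 + \sum_{j=d_i}^{d_i+D_i-1}\bigl(T_x(j) -
T_{th}\bigr)\Bigr],$$

which is positive for any strict exceedance and compresses the heavy upper
tail of summed exceedances. Because heat-related deaths trail the exposure,
each event is scored over its days plus up to $L$ *lag days*; when the
nominal lag window of one event would reach into the next event, the
overlapping days are attributed to the later event, so the realised lag
$L_i = \min(L,\ \text{gap to next event},\ \text{days to series end})$.
The event-mean mortality rate is then

$$\bar p_i = \frac{1}{D_i + L_i}\sum_{j=d_i}^{d_i+D_i+L_i-1} p(j),$$

and the free parameters $(\alpha, p_0)$ are estimated by ordinary least
squares in

$$\bar p_i = p_0 + M_i\,\alpha + \varepsilon .$$

Both the sum and the denominator of $\bar p_i$ use the realised $L_i$; using
the nominal $L$ in the sum would average days that the overlap rule has
already assigned to the following event.

The remaining free parameters $(T_{th}, L)$ are chosen by exhaustive grid
search — by default every combination of $T_{th} \in \{21, \dots, 50\}$ °C
and $L \in \{0, \dots, 14\}$ days — selecting the combination with the
largest $R^2$ (squared Pearson correlation of the OLS fit). Ties are broken
deterministically: smaller $L$ first (parsimony), then larger $T_{th}$ (more
intense events). The slope $\alpha$ is the population's *sensitivity* to
heat (excess rate per unit magnitude) and $M_i$ the *hazard* magnitude; their
product is the realised risk.

## Temperature indicators

Three daily-maximum indicators can drive the model.

**Air temperature** ($T_\mathrm{max}$) is used as observed.

**Wet-bulb globe temperature** (WBGT$_\mathrm{max}$) is defined as
$0.7\,T_w + 0.2\,T_g + 0.1\,T_a$, but black-globe temperature $T_g$ is not a
standard station observable, so the pipeline uses the empirical Korean
polynomial

$$\mathrm{WBGT} = -0.2442 + 0.55399\,T_w + 0.45535\,T_a - 0.0022\,T_w^2 +
0.00278\,T_w T_a,$$

with the natural wet-bulb temperature $T_w$ approximated from $T_a$ and
relative humidity by Stull's arctangent fit (`stull_wet_bulb()`, radians
throughout). The defining weighted average is kept as `reference_wbgt()` for
cross-checks. Stull's fit was calibrated at standard pressure for ordinary
surface conditions; we do not enforce its validity region, and
`stull_wet_bulb()` documents that caveat rather than guessing a hard
boundary.

**Perceived temperature** (PT$_\mathrm{max}$) is the air temperature of a
reference environment that would produce the same thermal perception as the
actual conditions. It is computed from the predicted mean vote (PMV) of a
steady-state human heat balance. Under steady state (no heat storage in skin
or core) the thermal load is

$$L_{th} = M - W - (C_\mathrm{skin} + R_\mathrm{skin} + E_\mathrm{skin}) -
(C_\mathrm{res} + E_\mathrm{res}),$$

and $\mathrm{PMV} = \alpha_\mathrm{pmv}(M) \cdot L_{th}$ with
$\alpha_\mathrm{pmv}(M) = 0.303\,e^{-0.036 M} + 0.0275$. On the heat branch
($\mathrm{PMV} \ge 0$),

$$\mathrm{PT} = 6.18\,\mathrm{PMV} + 16.83 .$$

The operational perceived-temperature product is built on a two-node
(core/skin) parameterisation whose coefficients are not published in a form
we could reproduce; `compute_pmv()` therefore implements the standard Fanger
steady-state balance — the structure the PMV equation above assumes — with
the published scale factor. The reference person is a 35-year-old male,
1.75 m, 75 kg, walking at 4 km/h (metabolic rate 135 W m⁻², no external
work) in summer clothing (0.5 clo). The relative air speed is the magnitude
of the vector sum of wind and the 1.11 m/s walking speed, taken as
orthogonal — the walking direction is unknown, and the orthogonal assumption
is the median over directions. The clothing-surface temperature is solved by
damped fixed-point iteration to $10^{-4}$ °C (at most 150 iterations;
non-convergence is an error carrying the residual). Against published
reference computations at standard comfort points the implementation agrees
to within a few hundredths of a PMV unit.

The cold branch ($\mathrm{PMV} < 0$) uses different published formulas and
is out of scope; `pt_from_pmv()` accepts the boundary $\mathrm{PMV} = 0$
(returning 16.83 °C) so the translation is continuous there, and errors on
negative input.

**Mean radiant temperature.** PT needs $T_\mathrm{mrt}$, which stations
rarely observe. `estimate_mrt()` is a deliberately simple pluggable default:
a clear-sky shortwave gain proportional to the sine of solar elevation
(up to 15 K at zenith), attenuated linearly by cloud fraction, with
$T_\mathrm{mrt} = T_a$ at night, under full overcast, or when cloud data are
missing (with a warning). The event model downstream consumes daily maxima
and none of its conclusions depend on this scheme; supply observed or
modelled $T_\mathrm{mrt}$ where available.

**Daily reduction.** `daily_max()` takes per-day maxima of the hourly
indicator. A day with fewer than 18 of 24 valid hours is marked missing
(configurable); sparse days would otherwise report spuriously low maxima.
Missing days terminate event runs — they never bridge two runs into one.

## Evaluation

For event $i$ the model's expected total deaths over the event + lag window
are

$$\hat N_{\mathrm{death},i} = N_i\,(M_i \alpha + p_0)\times 10^{-6}\,(D_i +
L_i),$$

with $N_i$ the window-mean population (annual population releases are
interpolated linearly between mid-years by `interpolate_population()`). The
$10^{-6}$ converts the modelled rate to a raw per-person daily rate.
Negative predictions, possible when the fitted line dips below zero, are
reported unclipped so residual diagnostics stay honest. Observed and
estimated per-event totals are compared by RMSE and by NRMSE = RMSE divided
by the mean observed total. Model selection and fitting use training years
only; `train_test_evaluate()` freezes $(T_{th}, L, \alpha, p_0)$ at the
chronological split and re-extracts events in the held-out years with the
frozen threshold and lag. A test period with no events is reported as empty,
not as an error.

The *annual mean excess mortality rate* is reported under the convention
$\mathrm{MEMR} = \sum_i M_i\,\alpha\,(D_i + L_i) / n_\mathrm{years}$
($10^{-6}\,\mathrm{year}^{-1}$): the excess person-time rate accrued per
year under the fitted model. Published tables of this quantity do not print
their aggregation formula; ours is one consistent reading, linear in
$\alpha$, and is labelled as a convention wherever it appears.

## The synthetic generator

Real station observations and mortality microdata are not redistributable,
so the package ships a generator that reproduces the *statistical structure*
the model assumes, making every pipeline stage testable and parameter
recovery measurable.

`gen_indicator_series()` draws daily maxima
$T_x(t) = \mu(t) + e(t)$ with a sinusoidal seasonal mean
$\mu(t) = a_0 + a_1 \sin\bigl(2\pi(\mathrm{doy} - \phi)/365\bigr)$ and
stationary AR(1) noise $e_t = \rho\,e_{t-1} + \mathcal N(0, \sigma^2)$. The
defaults emulate a Korean metropolis: $a_0 = 16.5$ °C, $a_1 = 13.5$ °C and
$\phi = 122$ put the seasonal daily-max mean near 3 °C in midwinter and
30 °C at the start of August; $\rho = 0.7$ and $\sigma = 3$ °C give the
day-to-day persistence and ~4 °C marginal spread typical of summer
daily-maximum series. Calendar dates are real (the 29 February seasonal
position is folded onto day 365) so train/test splits are exact calendar
years.

`gen_mortality()` draws daily deaths as Poisson with mean
$N \cdot \mathrm{rate} \times 10^{-6}$, where the rate is $p_0^*$ off-event
and $p_0^* + \alpha^* M_i$ uniformly across every day of event $i$'s
event + lag window. Defaults: $T_{th}^* = 33$ °C, $L^* = 4$ days,
$\alpha^* = 2$, $p_0^* = 10$ ($10^{-6}\,\mathrm{day}^{-1}$), $N = 10^6$.
Poisson counts are the natural noise model for small daily death counts;
note they induce heteroscedastic *rate* noise, whereas the fitting model
assumes additive homoscedastic error — a deliberate, documented mismatch
that mirrors real data. The generator calls the *same* event-extraction,
magnitude and lag-truncation code used by the fitter, so the generative and
fitted windows coincide exactly when the grid search lands on the truth
(structural identifiability). All randomness flows from the config seed
(the mortality stream uses a fixed deterministic offset of the same seed);
equal configs give bitwise-identical data.

What the generator does *not* emulate: demographic structure, day-of-week
and influenza seasonality in mortality, air-pollution confounding, spatial
correlation between cities, climate trends, and mortality displacement
("harvesting"). Green tests on synthetic data therefore validate the
machinery and its statistical behaviour under the stated assumptions, not
the epidemiological correctness of any real-world fit.

## Model selection: a known hazard, and a defaults decision

Selecting $(T_{th}, L)$ by maximising $R^2$ over ~450 combinations has a
sharp small-sample pathology. Under the null hypothesis of no relationship,
the $R^2$ of an $n$-event combination is distributed
$\mathrm{Beta}\bigl(\tfrac12, \tfrac{n-2}{2}\bigr)$; for $n = 3$ that
distribution puts ~20% of its mass above $R^2 = 0.9$. High thresholds
always contribute a few 3–5-event combinations, so an unconstrained search
almost surely "selects" one of them — with an absurd slope fitted through
three noisy points. We therefore require at least `min_events = 10` events
for a combination to enter selection (the per-combination null
$P(R^2 > 0.5)$ is then ~2%); `fit_event_regression()` itself only requires
the degrees-of-freedom minimum of 3. The floor is configurable via
`grid_spec()`.

Two further properties of max-$R^2$ selection survive any event-count
floor, and users should know them. First, a *winner's-curse bias*: the
slope at the selected combination is biased away from the truth (in our
recovery experiments the median $|\hat\alpha/\alpha^*|$ error is ~25%
even though the threshold itself is recovered within 1 °C in three
quarters of replicates, and the OLS slope at the *true* combination is
consistent). Second, *significance inflation*: the p-value of the selected
combination is not a valid test, because it is the best of hundreds of
correlated looks — with $\alpha^* = 0$ the selected slope reaches nominal
95% significance in roughly half of replicates. The per-combination
diagnostic table returned by `grid_search()` exists precisely so that the
selected fit can be judged against the whole $R^2$ landscape rather than
taken at face value.

## Numerical and degenerate-input choices

* Exceedance is strict ($T_x > T_{th}$); equality ends a run, consistent
  with magnitudes requiring positive increments.
* Grid-search results are independent of evaluation order; ties are broken
  by the documented deterministic rule.
* The per-combination path is implemented with cumulative sums (magnitudes
  depend only on $T_{th}$, window means are $O(1)$ per event); the test
  suite verifies it against the direct per-event path to $10^{-10}$.
* A combination whose events have zero magnitude variance is skipped, as is
  any combination below the event floor; if *no* combination is fittable,
  `grid_search()` errors ("no-model"), which the pipeline reports as a
  flagged stratum row rather than aborting other strata.
* Mortality missing on a day whose indicator is observed is an error
  (silent imputation would bias $\bar p_i$); joint missingness drops the
  day from the window mean.
* Problem sizes in the shipped tests — series of 8–30 synthetic years,
  20-replicate recovery experiments, 1000-case brute-force cross-checks —
  were chosen to exercise every code path at statistically meaningful scale
  while keeping the default suite fast.

## Limitations

The regression treats event-mean rates as homoscedastic although both the
Poisson counts and the varying window lengths make them heteroscedastic; a
weighted or count-model (Poisson/negative-binomial) variant would be the
natural extension. The selection hazards above mean the fitted $\alpha$ and
its stars should be read as descriptive, not inferential. PT here is the
standard-person heat branch only: no senior-specific reference person, no
cold-stress formulas, and the simplified radiation scheme stands in when
$T_\mathrm{mrt}$ is unobserved.
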