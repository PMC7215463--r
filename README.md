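# heatmort

Event-based modelling of heat-related excess mortality from daily maxima of
thermal-comfort temperature indicators.

Public-health agencies need to know how much mortality a heatwave adds, which
temperature indicator predicts it best, and at what threshold and with what
delay the effect acts. `heatmort` implements the full chain for an
event-based answer, aimed at environmental epidemiologists and biometeorology
groups:

1. **Thermal indices** — perceived temperature (PT) from a Fanger-type
   predicted-mean-vote (PMV) heat balance for a standard walking reference
   person (heat branch: PT = 6.18 PMV + 16.83); wet-bulb globe temperature
   (WBGT) from the empirical Korean polynomial
   WBGT = −0.2442 + 0.55399 Tw + 0.45535 Ta − 0.0022 Tw² + 0.00278 Tw·Ta,
   with Stull's arctangent wet-bulb approximation; plain air temperature.
   Hourly values are reduced to daily maxima with a completeness rule.
2. **Event model** — heatwave events are maximal runs of ≥ 3 days with the
   daily maximum strictly above a threshold T<sub>th</sub>; each event gets a
   log-scale magnitude M = log₁₀(1 + Σ exceedance) and an event-mean
   mortality rate over its days plus a lag window (truncated where the next
   event begins). OLS fits p̄ᵢ = p₀ + Mᵢ·α + ε; the (T<sub>th</sub>, L) pair
   is selected by exhaustive grid search (21–50 °C × 0–14 days) maximising
   R², with a minimum-event floor that keeps the selection away from
   meaningless tiny-event fits.
3. **Evaluation** — per-event expected deaths
   N̂ᵢ = Nᵢ(Mᵢα + p₀)·10⁻⁶·(Dᵢ+Lᵢ), scored by RMSE and NRMSE on a
   chronological train/test split with the fit frozen at the split.
4. **Synthetic data** — a seasonal + AR(1) weather generator and a Poisson
   mortality generator sharing the event code with the fitter, so the whole
   pipeline is testable end-to-end and parameter recovery is measurable.

Rates are carried in 10⁻⁶ · day⁻¹ throughout; slopes α in
10⁻⁶ · day⁻¹ · °C⁻¹ (per unit log-magnitude).

## Worked example

Simulate twenty years of a synthetic city (base mortality 10 per million per
day, true threshold 33 °C, lag 4 days, slope 2), fit on 2001–2016 and
evaluate on the held-out years:

```r
library(heatmort)

cfg  <- synthetic_config(n_years = 20, seed = 42)
ser  <- gen_indicator_series(cfg)
mort <- gen_mortality(ser, cfg)

res <- train_test_evaluate(ser, mort, grid_spec(), split_year = 2016)
res$fit
#> <heat_fit> Tmax: Tth = 31 degC, L = 4 d, alpha = 3.331, p0 = 7.032 (1e-6/day), R2 = 0.370 ***, 59 events
res$scores
#> # A tibble: 2 × 4
#>   period n_events  rmse nrmse
#>   <chr>     <int> <dbl> <dbl>
#> 1 train        59  10.7 0.114
#> 2 test         19  15.2 0.155
round(res$train_memr, 2)
#> [1] 128.64
```

Reading the output: the grid search selected a 31 °C threshold with a 4-day
lag — the lag is recovered exactly and the threshold lands 2 °C low, a
documented bias of max-R² selection (see the methods vignette); the slope
3.33 × 10⁻⁶ day⁻¹ means each unit of log-magnitude adds about 3.3 deaths per
million per day across the event window, against a base rate of about 7 per
million per day at this threshold's parameterisation. The fit is flagged
`***` (slope significant at the 95% level — descriptive only, since the
combination was selected post hoc). Held-out NRMSE of 0.155 means per-event
total-death predictions are off by ~16% of the mean observed event total.
The annual mean excess mortality rate under the fitted model is ~129 excess
deaths per million per year.

The index chain for a single observation:

```r
kma_wbgt(stull_wet_bulb(33, 60), 33)   # WBGT from Ta = 33 degC, RH = 60%
#> [1] 30.45033
pmv <- compute_pmv(ta = 33, rh = 60, wind = 1.5, tmrt = 40)
pt_from_pmv(pmv)
#> [1] 37.5781
```

Multi-stratum runs (cities × age groups) go through `run_pipeline()`, which
writes `fit_table.csv`, `evaluation.csv`, `events.csv` and a reproducibility
manifest; `pool_mortality()` builds aggregate strata. A thin command-line
wrapper over the same functions is at `inst/scripts/heatmort-cli.R`.

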