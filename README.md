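# coldharvest

Annual time-series estimation of cold- and heat-related mortality beyond
short-term displacement ("harvesting").

## The problem

Daily studies consistently find that mortality rises on and shortly after
cold or hot days. What they cannot tell is how much life those deaths
cost: if the victims were frail people who would have died within weeks or
months anyway, the excess is *displaced* mortality, not lost life. Daily
designs can detect displacement up to about a month; beyond that the
compensating deficit vanishes into seasonal noise.

`coldharvest` implements an annual design for this question, for
epidemiologists and biostatisticians working with long daily mortality and
temperature series. Deaths and degree-day temperature exposures are
aggregated into 52-week years anchored in early October, so a winter's
cold and its lagged deaths land in the same year. Any death displaced by
less than roughly a year cancels *within* a year; an association between
annual deaths and annual cold therefore measures only effects that outlast
the year. The package fits

    log E[Y_t] = a + b_C * C_t + b_H * H_t + s(t; df) + g * F_t + sum_j d_j * step_jt

a quasi-Poisson regression of annual deaths `Y_t` on annual cold `C_t` and
heat `H_t` (means of daily degrees below/above an 18 °C threshold),
with a natural-spline secular trend `s(t)` (1 df per decade), the annual
influenza death proportion `F_t`, and step indicators for administrative
discontinuities. Effects are reported as `100 (e^b − 1)` percent per °C.
For contrast it also fits the conventional short-time-scale analysis: a
conditional quasi-Poisson (time-stratified case-crossover) model of weekly
deaths on two-week-lagged cold and unlagged heat within year × month
strata, which captures the acute effect whether displaced or not.

A synthetic daily-data generator with a controllable displacement
mechanism (displaced fraction `f`, horizon `D` days) provides ground truth
for validating the whole inferential chain; a full sensitivity grid
(distribution family, spline flexibility, threshold, extra steps,
influenza control) mirrors standard practice.

## Worked example

Simulate a 57-year London-like series with boundary steps and half of the
cold-attributable deaths displaced by up to 60 days, then fit the annual
model:

```r
library(coldharvest)
g <- generate_dataset(
  mort_config = mort_sim_config(
    steps = data.frame(year = c(1965, 1966), factor = c(1.15, 1.08)),
    harvest = harvest_config(beta_cold = 0.017, f = 0.5, D = 60)),
  seed = 1)
annual <- build_annual_series(g$daily, steps = c(1965, 1966))
fit <- fit_annual(annual)
print(fit)
#> Log-linear count model (quasipoisson), n = 57
#> Percent increase per degree C (95% CI):
#>   cold    0.89% (0.63 to 1.16)
#>   heat    0.69% (-0.23 to 1.61)
#> Dispersion (Pearson) = 1.109   AIC = 811.6
```

The acute truth is `100 (e^0.017 − 1) = 1.71%` per °C of cold, but half of
those deaths were displaced by under 60 days — almost all within the
October-to-October year — so the annual design correctly reports only the
non-displaced half (0.89%). The displacement demonstration makes the
designed contrast explicit (expectation-mode series, acute truth 2.02%):

```r
displacement_demo(seed = 1)
#>   f   D acute_truth_pct annual_cold_pct weekly_cold_pct annual_ratio weekly_ratio
#> 1 0  60            2.02           2.122           1.719        1.050        0.851
#> 2 1  60            2.02           0.039           1.847        0.019        0.914
#> 3 1 400            2.02           0.872           1.994        0.432        0.987
```

With no displacement (`f = 0`) both estimators recover the truth (the
weekly one minus a known ~15% aggregation attenuation). With every
attributable death displaced by under two months (`f = 1, D = 60`) the
annual estimate collapses to 2% of truth while the weekly estimate keeps
91% — short-term harvesting is invisible to the weekly design but erased
from the annual one. With displacement beyond a year (`D = 400`) even the
annual estimate attenuates below half of truth: the design detects
precisely the deaths displaced beyond its year boundary.

`run_pipeline(daily, out_dir)` produces the full bundle (weekly/annual
tables, annual + weekly estimates per death stream, sensitivity grid,
residual diagnostics, run log), and `inst/exec/coldharvest` exposes the
same steps as shell subcommands (`simulate`, `build`, `fit-annual`,
`fit-weekly`, `sensitivity`, `demo`).

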