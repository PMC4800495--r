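# stomawave

How much of a simulated heatwave is a choice of stomatal conductance
scheme? Land surface models partition available energy between latent and
sensible heat, and over vegetated land that partition is controlled by
stomata. Most schemes let the two fitted constants of an empirical
conductance model vary only by photosynthetic pathway; leaf measurements
say water-use strategy varies by plant functional type (PFT). stomawave is
a desk-scale laboratory for the consequences: it implements both schemes,
couples them to a Farquhar C3 leaf and a daily big-leaf bucket column,
drives everything with a stochastic boreal weather generator, and measures
the control-versus-experiment response in percentile-based heatwave
indices with ensemble significance testing. It is aimed at land-surface
and climate-extremes researchers who want the full chain — leaf equation
to FDR-stippled difference map — small enough to read, test and rewire.

## The core models

The experiment arm uses the optimal-stomatal-theory scheme with a per-PFT
slope `g1` (kPa^0.5), the marginal carbon cost of water:

    gs = g0 + 1.6 (1 + g1 / sqrt(D)) A / Cs,   g0 = 0

The control arm is the pathway-level Leuning-type empirical scheme:

    gs = g0 + a1 A / ((Cs − Γ) (1 + D / d0)),  a1 = 9, d0 = 1.5 kPa (C3)

with `A` from a two-limitation Farquhar model (peaked Vcmax/Jmax response,
so photosynthesis shuts down in extreme heat) and `ci` closed by a
bisection solver on supply = demand. Heatwaves are runs of ≥ 3 days above
the calendar-day 90th percentile (15-day window, 30-year base); indices
are frequency, duration, intensity, max intensity, plus TXx. Ensemble
differences are tested per cell with Student's t and screened with
Benjamini–Hochberg field significance.

## Worked example

Estimate `g1` from a synthetic leaf gas-exchange survey (two PFTs, 10 %
measurement noise), close one leaf, then run a small paired ensemble:

```r
library(stomawave)

leaf <- generate_leaf_dataset(c(evergreen_needleleaf = 2.35, crop = 5.79),
                              n_obs = 200, noise_cv = 0.1, seed = 42)
fit_g1(leaf, by = "pft")
#>                  group   g1_hat         se   n
#> 1                 crop 6.016862 0.05171795 200
#> 2 evergreen_needleleaf 2.404609 0.02567341 200

solve_coupled(cs = 400, vpd = 1.2, leaf_temp = 22, par = 1400,
              photo = photo_params(vcmax_25 = 60),
              stomatal = stomatal_params("medlyn", g1 = 2.35))
#>   assimilation conductance_h2o      ci     residual
#> 1     13.75548       0.1730576 272.824 3.378631e-12

ex <- ensemble_experiment(n_members = 3, grid_rows = 4, grid_cols = 4,
                          years = 40, base_years = 30,
                          intervals = list(1:20, 21:40))
run_experiment(ex, seed = 7)
#> Paired ensemble difference report (experiment minus control)
#>   grid: 16 cells, 3 members, seed 7
#>   domain-mean differences:
#>     jja_tmax          +0.0446  (t = +1.40, p = 0.235)
#>     jja_et            -0.0379  (t = -7.43, p = 0.002)
#>     txx               +0.0767  (t = +1.25, p = 0.279)
#>     hw_frequency      -0.0026  (t = -0.09, p = 0.930)
#>     hw_duration       +0.0011  (t = +0.01, p = 0.991)
#>     hw_intensity      +0.0996  (t = +1.27, p = 0.272)
#>     hw_max_intensity  +0.0613  (t = +0.95, p = 0.395)
#>   FDR-significant cells (all intervals): hw_duration=0, hw_frequency=0,
#>   hw_intensity=0, hw_max_intensity=0, jja_et=2, jja_tmax=0, txx=0
```

Reading the report: the conservative-`g1` experiment transpires less
(`jja_et` down, and that is where the field-significant cells are), the
surface-temperature proxy warms, the warmest day of the year (`txx`) and
heatwave intensity respond more strongly than the summer mean, and
heatwave frequency/duration barely move — the qualitative fingerprint of
swapping the conductance scheme. Magnitudes are small by construction:
the column has no boundary-layer or precipitation feedback, so only signs
and orderings are meaningful.

The fitted `g1` table above also shows the estimator working: 2.40 ± 0.03
against a true 2.35, and 6.02 ± 0.05 against 5.79, from 200 noisy
observations each. `fit_g1()` also offers a two-stage
species-within-PFT estimator and a mixed-effects route (`method = "lme"`).

Per-PFT parameters live in `inst/extdata/pft_params.yaml`
(`read_pft_params()` loads it, or your own file); the weather generator,
column and experiment are configured through `weather_config()`,
`column_config()` and `ensemble_experiment()`.

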