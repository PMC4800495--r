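---
title: "Stomatal conductance schemes and simulated heatwave intensity: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stomatal conductance schemes and simulated heatwave intensity: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

stomawave asks a single question at desk scale: if a land surface swaps an
empirical stomatal conductance scheme whose two constants vary only by
photosynthetic pathway for an optimal-theory scheme whose slope varies by
plant functional type (PFT), how does the change propagate through
evapotranspiration into daily maximum temperature and heatwave statistics?
This vignette is the package's account of the models, the choices behind
their defaults, and what the synthetic experiments can and cannot show.

## The two conductance schemes

Both schemes couple stomatal conductance to net assimilation `A`
(µmol m⁻² s⁻¹), leaf-surface CO₂ `Cs` (µmol mol⁻¹) and vapour pressure
deficit `D` (kPa).

The **optimal-theory scheme** (`medlyn_gs()`) is

    gs = g0 + 1.6 (1 + g1 / sqrt(D)) A / Cs

with `g0 = 0`, leaving one parameter per PFT, `g1` (kPa^0.5), theoretically
the marginal carbon cost of water. Low `g1` means conservative water use.
The packaged defaults (`inst/extdata/pft_params.yaml`) are stand-ins
spanning the range of the published global leaf synthesis — tundra 2.22 and
evergreen needleleaf 2.35 at the conservative end, crops 5.79 at the
profligate end — and the YAML file is the single source of truth: edit it
or pass a replacement to `read_pft_params()`.

The **default empirical scheme** (`default_empirical_gs()`), the control,
is a Leuning-type form

    gs = g0 + a1 A / ((Cs − Γ) (1 + D / d0))

with pathway-level constants `a1 = 9`, `d0 = 1.5` kPa for C3 (also in the
YAML file) and Γ the temperature-adjusted CO₂ compensation point. The
published sources for the control model cite the scheme but not a complete
constant set for this configuration, so these widely used C3 values are
config-overridable rather than hard-coded.

Two structural contrasts drive everything downstream. First, at moderate
`D` the control conducts ~10–15 % more water than the conservative-`g1`
scheme, so the experiment transpires less and runs warmer. Second, their
relative VPD sensitivities −(1/gs) ∂gs/∂D differ: `1/(d0 + D)` for the
control versus `(g1/(2D^1.5))/(1 + g1/√D)` for the optimal scheme, so
beyond ~3 kPa the control loses conductance faster
(`vpd_sensitivity_compare()` reports both curves after calibrating the
schemes to agree at 1 kPa; rescaling the slope does not alter relative
sensitivities). Consequently the conductance gap narrows — and eventually
reverses — on the very driest days, which is why the placement of hot-day
VPD relative to this crossover (~2.2 kPa at `g1 = 2.35`) matters so much
for extreme-day statistics.

## Leaf photosynthesis

`net_assimilation()` is a standard two-limitation Farquhar C3 model: the
minimum of the Rubisco-limited and RuBP-regeneration-limited rates minus
day respiration, with a non-rectangular hyperbola light response
(θ = 0.7, α = 0.3 mol e⁻ mol⁻¹ photons). A hard minimum of the two
limitations was chosen over a smoothed minimum so every output can be
traced to one closed-form expression in tests. Kinetic constants default
to the Bernacchi in-vivo set (Kc 404.9 µmol mol⁻¹, Ko 278.4 mmol mol⁻¹,
Γ* 42.75 µmol mol⁻¹ at 25 °C, with their usual activation energies).

Vcmax and Jmax follow a peaked (deactivation) temperature response. The
paper-level anchor for this package is that photosynthesis is inhibited at
high leaf temperature (around 30 °C), which in turn damps the
between-scheme transpiration difference during extreme heat. The entropy
term defaults to `ds = 657` J mol⁻¹ K⁻¹ — the value entropy-acclimation
relations give for growth temperatures near 10 °C, typical of the boreal
study domain — which places the Vcmax optimum near 28 °C, the net-A
optimum near 22–23 °C, and complete shutdown (A ≤ 0) by roughly 40 °C.
Warm-adapted vegetation would warrant ~640 (optimum ≈ 36 °C); both `hd`
and `ds` are exposed in `photo_params()` and `peaked = FALSE` disables
inhibition entirely.

## The coupled solution

`solve_coupled()` closes the leaf: it finds the intercellular CO₂ `ci`
where diffusive supply `(gs/1.6)(Cs − ci)` equals biochemical demand
`A(ci)`, with `gs` depending on `A` through the selected scheme (the 1.6
factor converts the CO₂-side ratio to water vapour; the returned
conductance is for water). The root is bracketed on `[0, Cs]` and located
by bisection on interval width (to 1e-10 µmol mol⁻¹), not on the residual:
supply minus demand merely touches zero from above at the compensation
point, and a residual-based stop could accept that spurious tangency. A
leaf with `A(Cs) ≤ 0` (dark, frozen, or heat-inhibited) has no transpiring
root and returns `ci = Cs`, `gs = g0` — the gradient-free equilibrium.
Temperature-adjusted kinetics, electron transport and the conductance
factor are hoisted out of the loop, so an 80-year daily series solves in
one vectorised call (~0.1 s). Residuals are verified below 1e-6
µmol m⁻² s⁻¹, and tests compare `ci` against an independent 0.01-step grid
search.

## Estimating g1 from leaf data

`generate_leaf_dataset()` emulates a field synthesis: `A` uniform on
[2, 30] µmol m⁻² s⁻¹, `Cs` near 400 µmol mol⁻¹, `D` lognormal truncated to
[0.3, 4] kPa (a typical measurement envelope), species labels nested in
PFT, and mean-one multiplicative lognormal conductance noise with chosen
CV. `fit_g1()` estimates `g1` with `g0` fixed at zero. Because the model
is then linear in `g1`, the least-squares minimiser is evaluated in closed
form (an iterative nonlinear fit is identical where it converges, and
fails outright on zero-residual data). Two further estimators represent
the mixed-effects fitting used for the real synthesis: a transparent
two-stage route (species-level fits, then a precision-weighted PFT mean)
and a random-slope mixed model via `nlme::lme()` on the linearised form.
Recovery is verified exactly without noise and to a median relative error
well under 5 % at n = 200 per PFT with 10 % noise.

## The land-surface column

`run_column()` is a deliberately small, fully auditable daily column:

* **Leaf-to-canopy scaling.** The coupled gas exchange is solved at midday
  conditions (leaf temperature = forcing tmax, clamped to the kinetic
  domain [−10, 60] °C; midday PAR = shortwave × `par_factor`, default 8
  µmol J⁻¹ s⁻¹ m² accounting for the midday-to-daily-mean ratio) and
  multiplied by the prescribed monthly LAI — big-leaf scaling under
  prescribed phenology, as in the study design.
* **Transpiration.** A Penman–Monteith combination equation gives the
  daytime latent flux from available energy `(1 − albedo) SW`, VPD, a
  fixed aerodynamic resistance (50 s m⁻¹) and the canopy resistance;
  multiplied by the daylight fraction (0.45) it yields mm day⁻¹. Soil
  evaporation is neglected: ET is transpiration.
* **Bucket soil.** ET is capped by the current store (no root profile; all
  vegetation shares one drought behaviour, mirroring the study's own
  simplification); precipitation refills the bucket and the excess above
  capacity leaves as runoff. Water closes exactly:
  Σprecip − Σet − Σrunoff = ΔS to machine precision, checked to 1e-6 mm.
* **Temperature proxy.** Sensible flux is the energy-balance residual
  (latent + sensible = available energy, checked to 1e-6 W m⁻²), and
  `tmax_surface = tmax + (ra/ρcp)(H − H_ref)` — a linearised local
  adjustment (~0.04 K per W m⁻²), not a boundary-layer model. Only the
  sign and ordering of its responses are ever asserted; its magnitude
  calibration is unconstrained at desk scale.

`step_day()` exposes the identical one-day transition; a test folds it
manually and compares with the vectorised run.

## Synthetic weather

`generate_forcing()` produces the forcing the analysis assumes, on a
365-day calendar (no leap days — the usual GCM convention, and it keeps
calendar-day percentile bookkeeping exact): a sinusoidal seasonal cycle
peaking mid-July, an AR(1) anomaly (φ = 0.7, innovation SD 2.2 °C —
midlatitude-like persistence), and summer blocking episodes (Poisson
count, rate 1.2 per summer; geometric durations, mean 6 days) that add
warmth (+4 °C), clear-sky shortwave (+60 W m⁻²), dryness (−8 % RH) and
suppress rain. Midday VPD comes from Magnus saturation pressure at tmax
and a relative humidity that declines with the daily temperature anomaly
(base 70 %, −2 % per °C) — warm anomalies are dry, but the coupling is
kept maritime-boreal-moderate so blocking-day VPD sits near 1.5–2.2 kPa
in the default domain. Blocking uses an RNG stream seeded independently
of the base weather, so switching it off (or rescaling its warming)
leaves everything else bit-identical — the property the upper-tail tests
rely on. Precipitation is Bernoulli-exponential (mean 2.2 mm day⁻¹, wet
fraction 0.35), zeroed during blocking.

None of these distributions are constrained by the source study (its
forcing came from a climate model); they are artifact choices, and
everything is a `weather_config()` field. What the generator does *not*
emulate: spatial correlation between columns, sub-daily structure beyond
one midday value, humidity–precipitation coupling beyond the blocking
switch, and boundary-layer feedback of the surface state onto the
atmosphere. Passing tests therefore demonstrate the internal consistency
of the analysis chain under plausible forcing statistics, not skill
against real meteorology.

## Heatwave metrics

`calendar_thresholds()` computes, for each of 365 calendar days, the 90th
percentile of tmax pooled over a 15-day window (half-width 7, wrapping at
year edges) across a 30-year base — 450 values per calendar day — using
the linear-interpolation empirical quantile (type 7), fixed so oracle
tests are bit-stable. `detect_events()` finds maximal runs of ≥ 3 days
strictly above their calendar-day threshold; ties do not count. Events are
detected on the full year and attributed to summer by their start day
(JJA, days 152–243); the source text is silent on straddling events, and
start-day attribution is the documented choice. `heatwave_summary()`
returns, per year: frequency (events), duration (mean event length),
intensity (mean tmax over event days — pooled across events by default,
with the per-event-mean alternative exposed, since the verbal definition
admits both), maximum intensity, and TXx (warmest day of the year).
Summers without events report frequency 0 and *missing* duration and
intensity, never zero. `pdf_summary()` bins values on an absolute grid in
percent, so distribution shifts by a bin multiple translate the histogram
exactly.

## Significance testing

`cell_ttest()` is the pooled-variance two-sample Student test (the test
the study names; Welch is an option), with the convention that two
constant samples with equal means give p = 1. `fdr_field_mask()` applies
Benjamini–Hochberg step-up across grid cells at q = 0.05, matching the
95 % testing level — the study does not state q separately, and the
original BH procedure is used rather than any two-sided refinement. Both
are thin wrappers over `stats::t.test()` and `stats::p.adjust()`; the
tests verify them against closed-form arithmetic and a brute-force
enumeration, and a 1000-replicate global-null simulation checks the
any-rejection rate stays at q.

## The paired ensemble experiment

`ensemble_experiment()` + `run_experiment()` orchestrate the design: five
members (seed-staggered, the desk-scale analogue of year-apart
initialisation — the column has no slow state beyond the bucket, so seed
offsets are the honest equivalent), an 8×8 grid of independent columns on
a north–south transect (annual-mean tmax 0 → 6 °C; rows of tundra,
evergreen needleleaf, then deciduous needleleaf/larch — the cold belt
where a conservative-g1 experiment is conservative throughout the summer
VPD range), 80 years, CO₂ rising 410 + 6.6 (year − 1) µmol mol⁻¹ as the
high-emissions stand-in. The transient perturbs CO₂ only; the forcing
climate is statistically stationary by default (`warming_trend` is
available to superimpose warming, at the cost of pushing late-century
extreme days across the conductance crossover, where the experiment's
extreme-day advantage erodes — the convergence mechanism, visible in the
per-interval tables).

Control and experiment consume byte-identical forcing member-for-member;
thresholds come from each run's own first 30 years, per member and per
scheme separately, exactly as in the study design. Differences
(experiment − control) are averaged over four 20-year intervals, tested
per cell across members with Student's t, and screened with BH field
significance. Domain-level statistics use member domain means. Crop and
other profligate PFTs are deliberately absent from the default transect:
with `g1 ≈ 5.8` the optimal scheme out-conducts the pathway-level control,
so crop-dominated cells would reverse the regional ET signal; users who
want that contrast can pass `pft_rows` including `"crop"`.

With the defaults the chain reproduces the qualitative fingerprint the
acceptance suite asserts — summer ET down, the tmax proxy up, TXx
amplified relative to the mean response (hot blocking days combine
clear-sky radiation with below-crossover VPD, so the absolute latent-flux
gap is largest exactly on extreme days), heatwave intensity up, and
frequency/duration changes tiny and nowhere field-significant. Magnitudes
are of order 0.01–0.1 °C — roughly thirty-fold smaller than the source
study's coupled-model response, as expected with no boundary-layer or
precipitation feedback; only signs and orderings are claimed.

## Numerical choices and degenerate inputs

* Bisection to 1e-10 µmol mol⁻¹ interval width; residual guard 1e-6.
* VPD floor 0.05 kPa before √D (clamped, not an error).
* Negative assimilation clamps conductance at g0 ≥ 0, never negative.
* Strict threshold exceedance; quantile type 7 throughout.
* Empty groups, sub-10-observation fits, gappy base series, overlapping
  intervals, and out-of-capacity initial stores are errors; degenerate
  designs (no A signal) warn and return NA rather than a number.
* All generators take explicit integer seeds and restore the caller's RNG
  state; identical seeds give bit-identical output.

## Problem sizes

The test suite runs the full 5-member, 8×8-cell, 80-year paired experiment
(640 column runs, ≈ 19 million column-days) in about two minutes, the
1000-series brute-force audit of the heatwave machinery in under a minute,
and the 50-replicate g1 recovery study in seconds; these sizes were chosen
so the whole chain is exercised at full fidelity while remaining
comfortable on one CPU. `scripts/acceptance.R` re-runs the same
computations from scratch for any seed.

## Known limitations

A single linearised temperature proxy stands in for the boundary layer, so
absolute temperature responses are indicative only; soil moisture does not
down-regulate g1 (listed as future work by the source study, and out of
scope here); C4 photosynthesis, mesophyll conductance and triose-phosphate
limitation are not represented; columns are spatially independent, so
field significance operates under an independence assumption real grids
violate; and the empirical scheme's constants are representative rather
than tied to one archived model version.
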