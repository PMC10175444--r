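---
title: "Methods: gradient-based GEM flux inference and its uncertainties"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gradient-based GEM flux inference and its uncertainties}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gemflux)
library(dplyr)
```

## The problem

Forests are the dominant terrestrial sink for atmospheric gaseous
elemental mercury (GEM, Hg⁰), but direct ecosystem-scale GEM flux
measurements are rare. The workhorse technique is the aerodynamic
gradient method (AGM): GEM is measured at two heights above the canopy
(and, with a second system, above the forest floor), and the vertical
concentration difference is converted to a flux using
Monin–Obukhov similarity theory. `gemflux` implements the complete
inference chain from raw analyzer samples to annual deposition totals
with confidence intervals, plus the bookkeeping that turns those totals
into ecosystem mercury budgets.

## The flux-gradient model

The 30-min flux is

$$F \;=\; \frac{-\,u_*\,k\,(C_2 - C_1)}
  {\ln\!\frac{z_2-d}{z_1-d} \;-\; \Psi_h(\zeta_2) \;+\; \Psi_h(\zeta_1)}$$

with $u_*$ the friction velocity (m s⁻¹), $k = 0.4$ the von Karman
constant, $C_2, C_1$ the upper/lower inlet concentrations (ng m⁻³),
$d$ the zero-plane displacement height, and $\Psi_h$ the integrated
similarity function for heat evaluated at each inlet's stability
$\zeta_i = (z_i - d)/L$. The sign convention is micrometeorological:
higher concentration aloft means downward transport, i.e. a negative
flux (deposition); emission is positive. GEM fluxes are reported in
ng m⁻² hr⁻¹ (the SI per-second value times 3600); CO₂ fluxes processed
by the same machinery stay in µmol m⁻² s⁻¹ and serve to validate the
gradient core against an independently measured reference flux.

For $\Psi_h$ we use the Businger–Dyer forms: $\Psi_h = -5\zeta$ for
stable stratification ($\zeta \ge 0$) and
$\Psi_h = 2\ln[(1+x^2)/2]$, $x = (1-16\zeta)^{1/4}$, for unstable
($\zeta < 0$). These are the standard AGM choice; the functions are
continuous at neutral with $\Psi_h(0)=0$. The supplied $z/L$ is taken
to refer to `zeta_height` (default: the upper inlet) and is rescaled
linearly in $(z-d)$ to each inlet. When $d$ is not given it defaults to
2/3 of canopy height, the usual rule of thumb. The implied scalar eddy
diffusivity $K = u_* k\,(z_2 - z_1)/\text{denominator}$ is exposed for
diagnostics and is exactly consistent with the flux equation on the
geometric inlet separation.

## The QC chain

Processing order is fixed and mirrors standard gradient-system
practice:

1. **Trap-wise averaging.** Mercury analyzers alternate between two
   gold traps with slightly different calibrations. Within each 30-min
   window, 5-min samples are averaged per trap at each height, each
   trap's gradient is formed, and the per-trap gradients are averaged.
   This cancels trap offsets that would bias a pooled mean whenever
   trap and inlet height are unevenly crossed (e.g. after dropouts).
   Single-trap windows are used but flagged.
2. **Gradient outlier screen.** Robust median/MAD rule: reject where
   $|x-\tilde{x}| / (1.4826\,\mathrm{MAD}) > 3.5$. The threshold is
   scale-free and standard for flux QC; the screen is applied within
   calendar-month × hour-of-day cells so that diel and seasonal
   structure is not mistaken for spikes. A zero-MAD (degenerate) cell
   removes nothing.
3. **Stability screen.** Records with $z/L < -2$ or $z/L > 1$ are
   removed; the bounds themselves are retained (the removal condition
   is strict, so the acceptance interval is closed).
4. **Flux computation**, then a **second outlier screen** on fluxes.
5. **Gap filling.** Each missing 30-min flux is replaced by the median
   of measured fluxes in the same calendar month (years kept separate)
   and hour-of-day. Measured values are never altered; unfillable cells
   stay missing and are reported.

Every record carries exactly one of the flags `ok`,
`stability_rejected`, `outlier_rejected`, `gap_filled`, `missing`
(pre-fill reasons are preserved in `orig_flag`), so flag counts always
close to the series length.

## Partitioning and accumulation

Canopy fluxes are the pointwise difference between the whole-ecosystem
and forest-floor series on the shared grid, so cumulative sums are
additive across compartments by construction. Day/night partitioning
uses PAR > 5 µmol m⁻² s⁻¹ (configurable; records with missing PAR fall
back to positive solar elevation and are counted). Cumulative fluxes
are direct sums, $\sum F \cdot 0.5\,\mathrm{hr} / 1000$ in µg m⁻²; for
records longer than 12 months, calendar months observed in two years
are averaged before forming the annualized sum. Growing-season labels
are configured calendar windows (April–October coniferous,
June–October deciduous by default), not phenology inferred from the
data.

## Random error and confidence intervals

Random flux error is estimated by daily differencing: pairs of measured
(never gap-filled) records exactly 24 h apart whose PAR agrees within
75 µmol m⁻² s⁻¹ and $u_*$ within 0.1 m s⁻¹, so the true flux largely
cancels and the difference is dominated by twice the random error.
Errors are modelled as Laplace (double-exponential), the
characteristically heavy-tailed shape of flux measurement error. For
iid Laplace($\beta$) per-record errors the difference $d = e_1 - e_2$
has $E|d - \mathrm{med}(d)| = 1.5\beta$, so we estimate
$\hat\beta = \mathrm{mean}|d - \mathrm{med}(d)| / 1.5$ — robust, and
exactly unbiased under the declared model (a √2-based convention is
common for Gaussian errors but is biased by +6% for the Laplace case,
which matters when scale recovery is checked to percent level).

Intervals for cumulative sums come from Monte Carlo: each replicate
adds an iid Laplace draw per record (gap-filled records at twice the
scale, a deliberately conservative allowance for imputation error) and
the 2.5/97.5 percentiles of the replicate totals give the 95% CI,
reproducible under a fixed seed. Because the gradient-flux error scales
with $u_* k / D$, it is strongly diel; the end-to-end wrapper
`estimate_annual_flux()` therefore fits separate day and night scales
and propagates per-record — with a single pooled scale the interval
would be dominated by the (much larger population of) night pairs and
markedly too narrow. Heteroscedasticity beyond the day/night split is
not modelled by default.

## The synthetic generator

`scenario_config()` + `simulate_scenario()` produce a fully specified
year: solar-geometry PAR with a random cloud factor; $u_*$ with a
day/night contrast; $z/L$ unstable by day, stable by night, with a
configurable excursion rate beyond $[-2, 1]$ to exercise the stability
screen; canopy GEM uptake as a rectangular-hyperbola light response
scaled by a smooth seasonal weight and coupled to the same assimilation
proxy that drives the simulated NEP (so growing-season cumulative GEM
and NEP correlate, as observed over real forests); a nocturnal canopy
term and a forest-floor flux of configurable sign; and observations
obtained by inverting the flux equation into 5-min samples with 10-min
inlet switching, alternating traps with calibration offsets, additive
Laplace concentration noise, and randomly dropped windows.

Preset conditions: the coniferous-like preset (growing season
April–October, nocturnal canopy deposition, floor a small source of
≈0.9 µg m⁻² yr⁻¹) yields annual ecosystem deposition of ≈13 µg m⁻²;
the deciduous-like preset (June–October, nocturnal canopy emission,
floor a sink of ≈10 µg m⁻² yr⁻¹) yields ≈25 µg m⁻². The uptake
coefficients (11.9 / 21.4 ng m⁻² hr⁻¹ at light-and-season saturation)
were fixed once from the light-response integral to land on those
annual totals. The default concentration noise scale
(0.0012 ng m⁻³ per 5-min sample) was chosen so the propagated annual
CI half-width is of order ±0.8 µg m⁻² on the ≈13 µg m⁻² signal, the
reported precision class of multi-year tower records; the default gap
fraction is 20%.

What the generator does *not* emulate: storage and advection below the
measurement heights, correlated (red-noise) measurement error,
instrument drift between calibrations, non-stationarity within 30-min
windows, and weather-driven synoptic flux variability beyond the cloud
factor. Passing recovery tests therefore demonstrates the correctness
of the inference chain, not that field records of this kind are free of
those systematic effects.

## Numerical choices and degenerate inputs

- Records with missing concentration, missing $z/L$, $u_* = 0$, or a
  non-positive stability-corrected denominator become flagged-missing
  fluxes, never exceptions; a zero gradient is a valid zero flux.
- The outlier screen's MAD = 0 guard leaves constant series untouched.
- Fewer than 30 daily-difference pairs triggers a warning and doubles
  the fitted scale (wide-uncertainty fallback); zero acceptable pairs
  is an error.
- Monte-Carlo propagation refuses fewer than 100 draws; percentile CIs
  at the default 400 draws carry ≈5% sampling noise on the half-width.
- All timestamps are local standard time; no daylight-saving handling
  is attempted inside a record.

## Worked example

```{r example, eval = FALSE}
cfg <- scenario_config("coniferous", seed = 1)
sc <- simulate_scenario(cfg, compartments = "ecosystem")
est <- estimate_annual_flux(sc$samples_ecosystem, sc$met_ecosystem,
                            cfg$site_ecosystem, seed = 1)
est$annual
# total ≈ -13.4 ug m-2, half_width ≈ 0.8 ug m-2 — the interval covers
# the generator truth (sum(sc$truth$ecosystem) * 0.5 / 1000)
```

Problem sizes used throughout the test suite: one simulated year
(17,520 half-hourly records, ≈105,000 5-min samples) per replicate for
recovery checks, 200 seeded replicates for interval-coverage
estimation, and 10⁵ paired differences for error-scale recovery.

## Known limitations

- The $z/L$ rescaling between inlet heights assumes the supplied
  stability refers to a single stated height; profiles of $L$ are not
  supported.
- The understory gradient system is processed with the same similarity
  forms as the above-canopy system; within-canopy turbulence violates
  Monin–Obukhov assumptions to a degree that only a field
  intercomparison could quantify.
- Gap filling by month-by-hour medians slightly damps extremes; with
  20% random gaps the induced bias on annual sums is small relative to
  the random-error interval, but structured (non-random) outages would
  bias it more.
- The mass-balance tools are bookkeeping over user-supplied component
  fluxes; they inherit whatever systematic errors those components
  carry.
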