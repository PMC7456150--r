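---
title: "Models and methods behind peatthaw"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind peatthaw}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(peatthaw)
```

peatthaw is an inventory-and-projection framework for northern peatland
carbon and nitrogen under permafrost thaw. This vignette explains the
models, the provenance and meaning of every tunable parameter, the
numerical conventions, and the limits of what the synthetic test bed can
demonstrate.

## The problem

Northern peatlands hold a peat C stock of the order of 400 Pg, roughly
half of it in peatlands underlain by permafrost. Whether that C stays in
the ground depends on climate: permafrost keeps deep peat frozen, and
thaw mobilises it. The package chains five pieces: (1) a landscape
description (peat cover, permafrost fraction, MAAT, peat depth), (2)
depth-to-storage models and area-weighted stock accounting, (3) an
equilibrium permafrost-fraction curve driven by MAAT, (4) a staged
transition model of what thaw does to C and N fluxes, and (5) an
impulse-response radiative-forcing engine that turns flux trajectories
into W m^-2^.

## The synthetic landscape

Real inputs to such an inventory are large raster products. To make every
downstream stage testable without downloads, `generate_landscape()` draws
a landscape with the statistical structure of the observational
compilations:

* **Domain.** 500 x 500 cells of 100 km^2^ (10-km cells), a 25 Mkm^2^
  extratropical domain. A latitudinal MAAT gradient spans -25 to +10 C
  with N(0, 2 C) cell noise, covering the full climate space in which the
  thaw thresholds operate.
* **Peat cover.** The peatland areal fraction follows a Gaussian climate
  profile centred at -3 C MAAT (width 7 C), modulated by lognormal noise
  (sdlog 0.6) and thresholded at 1%. The scale (0.31) was set once so the
  domain carries ~3.7 Mkm^2^ of peatland, of which ~1.7 Mkm^2^ is
  permafrost-affected — the proportions of the mapped inventory. Peat is
  concentrated in the boreal belt, which is what makes the regional flux
  numbers meaningful.
* **Peat depth.** Truncated normal with a 40-cm floor (the organic-depth
  threshold that defines a peatland). The underlying mean is solved
  numerically so that the *post-truncation* mean equals the configured
  249 cm; otherwise the floor would bias the sampled mean upward by ~4 cm.
  SD 97 cm.
* **Permafrost fraction.** Evaluated from the central equilibrium curve
  at the cell MAAT, plus N(0, 0.05) noise, clipped to [0, 1] and set to
  zero above +1 C MAAT (the warm cutoff used in map construction).
* **Cores.** `sample_peat_cores()` draws cells proportional to peat
  area and assigns bulk density (lognormal, median 0.09 g cm^-3^, sdlog
  0.35) and organic C content (truncated normal, 45 +/- 10 %, bounds
  10-60 %) — typical peat values; the combination gives a core C-storage
  mean of ~106 kg C m^-2^, matching the observed core compilation. N
  content uses 1.5 +/- 0.8 % with a 0.2 % floor.

**What the generator does *not* emulate:** spatial autocorrelation beyond
the latitudinal gradient, the negative depth difference between
permafrost and permafrost-free peatlands (~80 cm in observations; depths
here are drawn from one distribution), coastlines/soil maps, and any
real geolocation. Tests passing on this landscape validate the model
machinery and the shipped calibration, not the mapped products
themselves; the headline map-derived stocks (e.g. 415 Pg C) additionally
depend on machine-learning depth upscaling that is out of scope here.

## Stocks

`fit_storage_model()` is ordinary least squares of storage on depth.
Shipped defaults use zero intercepts and slopes anchored at the inventory
class means: C 115/249 kg C m^-2^ per cm shared across classes; N
1.9/286 (permafrost-free) and 4.2/205 (permafrost), class-specific
because N storage differs by more than 2x at similar depth. The exact
regression coefficients behind the original maps are unpublished, so the
defaults are anchors, overridable by refitting. `aggregate_stocks()`
weights each cell by `cell_area * peat_fraction` and splits it into
permafrost-affected (`x permafrost_fraction`) and permafrost-free parts;
totals are exact sums, so class totals add to the overall total to
machine precision. Note that class-mean N storages in the summary are
computed from each cell's single blended `n_storage` field, so the
class contrast appears in predictions, not in the re-partitioned cell
fields. Uncertainty is reported as a trimmed RMSE: residuals outside
their 5th-95th percentile band are discarded, weights renormalised, and
the weighted RMSE taken.

## The permafrost curve

Equilibrium permafrost fraction follows

$$f(T) = \tfrac12 f_{max}\,\mathrm{erfc}\!\left(\frac{T+\mu}{\sqrt{2}\,\sigma}\right),$$

a normal-CDF-shaped decline with MAAT. Shipped triplets: central
$(\mu, \sigma, f_{max}) = (1.95, 7.35, 0.92)$, upper $(0.70, 6.10,
0.96)$, lower $(3.10, 4.50, 0.86)$. Two conventions exist for the
denominator; the `sqrt(2) sigma` form is the default because the literal
$2\sigma^2$ reading produces a near-flat curve inconsistent with the
sharp thaw thresholds the projections exhibit; the literal variant stays
available via `convention = "literal"` for sensitivity analysis. The
fitted $\sigma$ envelopes are non-monotone (7.35 central vs 6.1/4.5);
this is recorded as-is from the source fits, not rationalised.

`fit_permafrost_curve()` minimises fraction RMSE with bounded multi-start
L-BFGS-B (mu in [-10, 10], sigma in (0, 20], f_max in (0, 1]), ties
broken by RMSE, then convergence, then smallest sigma. Per-pixel fitting
is the default; a MAAT-binned variant (`binned = TRUE`) is available
because the source description is ambiguous between the two.

`project_permafrost_extent()` maps global warming stabilization levels to
cell MAAT via a uniform polar-amplification factor (default 2.0). This is
a deliberate structural simplification of the ensemble ESM spatial
patterns the original projections used. The mapped climate is assumed in
quasi-equilibrium with the +0.5 C world (the 1960-1990 normal), so
`dT = 0.5` reproduces the present-day extent identically. The +1 C warm
cap is applied in mapping and projection, not inside the bare curve,
mirroring its role in map construction. Being an equilibrium model, it
says what extent will eventually be lost, not how fast.

## Baseline fluxes

Long-term net C uptake is a logistic function of MAAT,
`k / (1 + exp(-r (T - m)))`. The source fit's parameters are
unpublished; defaults k = 65 g C m^-2^ y^-1^, r = 0.25 per C, m = -4 C
were chosen once so that the peat-area-weighted mean over the default
landscape is ~34 g C m^-2^ y^-1^, the reported regional mean, with the
midpoint placed in the boreal MAAT range so rates saturate in temperate
climates. (A midpoint at +4 C, sometimes suggested, would require the
peat-weighted MAAT to sit near +6 C to average 34 — incompatible with a
northern peat distribution.)

CH~4~, N~2~O and lateral fluxes come from a stage x type table
(`default_stage_flux_table()`): five stages (intact permafrost,
active-layer deepening, young thermokarst, stabilized post-thaw,
nonpermafrost) by two types (minerotrophic fen-like, ombrotrophic
bog-like). The source synthesis values are unpublished, so the defaults
are calibrated: CH~4~ entries (nonpermafrost 19/6, intact 1.0/0.4,
thermokarst 30/18, stabilized 22/10 g C m^-2^ y^-1^) reproduce the
regional source of ~0.026 Pg C y^-1^ with the fen > bog >> intact
ordering seen in flux syntheses; N~2~O and lateral entries land near the
reported regional totals (0.022 Tg N, 0.022 Pg C, 0.7 Tg N per year).
Type shares per biome (tundra 0.70/0.30, boreal 0.55/0.45, other
0.50/0.50) are placeholders for unpublished mapping, config-first.
`baseline_flux_budget()` weights intact-permafrost vs nonpermafrost
occupancy by each cell's permafrost fraction; the CO~2~ term always
comes from the accumulation model (the long-term net balance), never
from the table.

## Thaw scenarios

Once a cell's thaw threshold is crossed, its thawed area (the decline in
equilibrium fraction between +0.5 C and the target warming) moves through
stages: active-layer deepening for 25-75 y (mean 50; ~1 cm y^-1^ through
25-75 cm to ice-rich peat), then — on the thermokarst pathway (default
half of the thawed area) — young thermokarst for 50-150 y (mean 100),
then stabilized; the other half takes an extended active-layer-deepening
route (twice the ALD duration) directly to the stabilized stage.
Deterministic mode uses the means; sampled mode draws triangular
durations over the ranges. Because cumulative fluxes are linear in the
durations and the triangular mode equals the mean, the deterministic run
equals the sampled expectation. Occupancies are exact interval overlaps
with annual steps, so they always sum to one.

The chronosequence loss model says the fraction of prethaw C lost within
100 y of thaw is `min(1, 1.1451 x^-0.0771)` of the prethaw stock x
(kg C m^-2^) — about 0.8 at typical stocks, with full loss below
x = 5.8. Taken literally over the whole stock this contradicts the
landscape-average losses of 11-18 kg C m^-2^ per thawed unit inferred
from the same chronosequences, so only an `eligible_fraction` (default
0.18) of the stock is subject to the loss; with typical permafrost
stocks of ~95-115 kg C m^-2^ this lands the per-unit average at ~16
kg C m^-2^, inside the observed band. The parameter is prominently
exposed because the reconciliation (stage probabilities? an eligible
layer?) is genuinely unresolved. Losses are routed to the lateral
(DOC/POC) pathway by default — flux observations do not support gaseous
losses of this magnitude — released uniformly over the 100-y horizon
(only the integral is constrained); `co2_route_fraction` can route part
to CO~2~ for sensitivity runs. The chronosequence loss applies to all
thawed area regardless of pathway; the pathway split only affects stage
GHG occupancy. N losses scale from C losses by class C:N ratios
(defaults 108/4.2 ~ 25.7 for permafrost, 123/1.9 ~ 64.7 for
permafrost-free peat). During active-layer deepening, an additional
N~2~O release proportional to the CO~2~-C release (`n2o_c_ratio`,
default 0.001 g N per g C) implements the mesocosm-derived scaling; the
default keeps scenario N~2~O forcing minimal, as observed.

All reported scenario series are net changes relative to the
intact-permafrost baseline of the same area (table fluxes plus
accumulation at unshifted MAAT). New-C gains in the thermokarst and
stabilized stages use the accumulation model at the shifted MAAT; the
flux table's CO~2~ entries for those stages are reference values only and
are not added on top (that would double-count). The old-C pool ledger —
initial stock minus cumulative gaseous and lateral old-C losses — closes
identically every year; tests verify closure below 1e-9 relative.

## Radiative forcing

`burden_perturbation()` convolves emitted masses with decay kernels:
single lifetimes for CH~4~ (12.4 y) and N~2~O (121 y), the four-term AR5
impulse response for CO~2~ (permanent fraction 0.2173; decaying fractions
0.2240/394.4 y, 0.2824/36.54 y, 0.2763/4.304 y). Fluxes enter as element
masses (C, C, N), are converted to molecule masses (x44/12, x16/12,
x44/28), then to mixing ratios (2.124 Pg C per ppm CO~2~; 2.75 Tg per
ppb CH~4~; 4.81 Tg per ppb N~2~O). Forcing is efficiency x burden
(1.37e-5 / 3.63e-4 / 3.00e-3 W m^-2^ ppb^-1^), with CH~4~ multiplied by
1.65 for its indirect effects. These are the AR5 values; the original
study used a variant parameterization whose exact modifications are
unpublished, which is why the headline forcing diagnostics carry generous
tolerances.

Numerical convention: emissions are uniform over each annual step and
burdens are reported at step edges, i.e. the kernel is evaluated at
midpoint lags. This single choice makes the burden zero at t = 0, makes a
sustained single-lifetime flux F converge to the analytic steady state
F tau (the discrete sum gives 12.396 vs tau = 12.4 — 0.03 % — where an
edge-lag sum would be 4 % high), and admits an exact closed-form pulse
oracle. Halving the step changes the present-day peak by well under 1 %.

"One year of present-day exchange" is implemented as fluxes held constant
in time: a literal single-year pulse of these small fluxes cannot peak
decades later, while the sustained budget peaks at +0.074 W m^-2^ after
~39 y (CH~4~-driven) and crosses into net cooling at ~380 y (CO~2~
sequestration wins) — the reported decadal-warming/centennial-cooling
behaviour. `compare_to_anthropogenic()` treats the anthropogenic forcing
trajectory strictly as an input series (the shipped
`anthropogenic_forcing_synthetic.csv` is a labelled synthetic stand-in
for external climate-policy model output).

## Problem sizes and determinism

The default landscape (250,000 cells) generates in about a second;
scenario runs aggregate cells before the time loop, so a 400-y scenario
costs milliseconds beyond the landscape itself. Tests use 40 x 30
landscapes where the default is not required and 500 Monte-Carlo draws
for the sampled-vs-deterministic equivalence. Every random draw is
seeded; identical config plus seed gives bit-identical landscapes, cores
and serialized outputs, and internal draws save and restore the caller's
RNG state.

## Known limitations

Equilibrium-only permafrost response (no thaw dynamics or transient soil
thermal model); uniform polar amplification instead of ESM warming
patterns; no fire, drought, hydrological routing, or new peatland
formation; lakes are absorbed into the thermokarst stage rather than
modelled separately; flux-table and eligibility defaults are calibrated
reference values pending the underlying synthesis tables; depth is not
class-specific between permafrost and permafrost-free peat; grids are
abstract cells without projections or CRS handling.
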