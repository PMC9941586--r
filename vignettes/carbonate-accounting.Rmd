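---
title: "Accounting for pelagic calcium carbonate: from plankton counts to a global budget"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Accounting for pelagic calcium carbonate}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pelagicarb)
```

## The problem

Planktonic calcifiers — coccolithophores, planktonic foraminifera, shelled
pteropods and heteropods — control how much CaCO~3~ the surface ocean
produces, and the balance between its shallow remineralisation and its
export to depth shapes ocean alkalinity and the air-sea CO~2~ balance.
`pelagicarb` implements the full accounting chain from raw shipboard
observations to a global production estimate:

1. **Conversion** of raw observations to CaCO~3~ mass: shell lengths through
   family-specific allometric fits and a carbon chain; filter counts through
   filter geometry and a coccolith mass table; picked foraminiferal weights
   taken as pure CaCO~3~.
2. **Standing stocks**: volumetric (mg m^-3^) and depth-integrated
   (mg m^-2^) inventories per taxon and station.
3. **Production**: stock divided by a turnover time carrying a flat prior,
   propagated by Monte-Carlo simulation; snapshot rates deflated to annual
   means by seasonal bias factors; unit conversion to mol m^-2^ yr^-1^.
4. **Skew-robust basin statistics** for large biomass compilations:
   zero-truncated kernel densities, bootstrap, and skewness.
5. **Global extrapolation**: an OLS regression of station production on
   satellite PIC, applied to a global climatology with exact spherical area
   weighting, plus a low-PIC minimum estimate.
6. **Export comparison**: production against sediment-trap fluxes,
   aragonite fractions, and loose-coccolith residence times.

A synthetic-data generator emulates every input with known ground truth, so
the whole chain is testable offline.

## Conversion models and their constants

For the shelled gastropods, per-individual CaCO~3~ follows from shell
length L (mm):

* Cavoliniidae: WW = 0.2152 L^2.293^; Carinidae: WW = 0.0888 L^2.161^
  (wet weight, mg);
* Limacinidae: DW = 0.1365 L^1.501^ (dry weight, mg);
* Cymbuliidae: DW = 0.0392 L − 0.003;
* Atlantidae: CaCO~3~ = 0.769 e^0.0023 L^ directly (an ash-weight fit).

Weights enter a carbon chain DW = 0.28 WW, POC = 0.25 DW,
PIC = POC × (PIC:POC), CaCO~3~ = 8.33 PIC, where 8.33 is the molar-mass
ratio M(CaCO~3~)/M(C). The PIC:POC partition 0.27:0.73 is read as fractions
of total carbon, so the chain multiplies POC by 0.27/0.73; heteropods use
the midpoint (0.365) of their published 0.28–0.45 range. Three choices here
were genuinely open:

* **Cymbuliidae clamp.** The linear dry-weight fit goes negative below
  L ≈ 0.077 mm. Tiny juveniles are legitimate inputs, so the conversion
  clamps to zero and warns rather than erroring.
* **Atlantidae length unit.** As printed, the exponential with L in mm is
  nearly flat over realistic lengths (~0.77 mg regardless of size), which
  sits oddly with the reported fit quality; the intended unit may be µm.
  The fit is implemented exactly as printed, with a configurable length
  scale (`atlantidae_length_scale`) rather than a silent unit guess.
* **Coccolith masses are data, not code.** Coccoliths-per-sphere and
  per-coccolith masses vary by species and calcification state, and the
  published per-species values live in cited compilations. They ship as an
  editable table/YAML config (`coccolith_mass_table()`), with placeholder
  defaults (20 coccoliths per sphere, 2.5 pg per coccolith) typical of a
  small bloom-forming species.

Cell concentrations follow the filter-geometry identity
F·C/(A·V) (effective filtration area × count / counted area × volume).
Foraminiferal test weight is taken as pure CaCO~3~: dry cytoplasm has no
significant effect on test weight, and empty tests are excluded upstream at
the counting stage.

## Standing stocks

Tow volume is net mouth area times flowmeter distance; the oblique tow is
treated as a column-integrating sampler, so areal stock is the
split-corrected concentration times the maximum tow depth. Bottle-cast
profiles are integrated trapezoidally from the first (shallowest) sample
to the depth where fluorescence falls to 1% of its peak — computed as the
shallowest such depth *below* the fluorescence maximum, linearly
interpolated between cast depths — and never extrapolated above the first
bottle or below the deepest one. If the 1% depth falls between samples,
the profile is interpolated at the bound.

## Production and its uncertainty

Production is standing stock over turnover time (days), under an
approximate steady-state assumption. Turnover carries a deliberately
conservative flat prior: 5–16 d for pteropods and heteropods, 14–28 d for
foraminifera (a 10–30 d variant is selectable, since both ranges are in
circulation). For coccolithophores the prior is placed on the **cell
division rate** (uniform 0.1–1.5 d^-1^) and inverted, giving turnover
support [0.67, 10] d. This is a consequential choice: a flat prior on the
rate concentrates probability at short turnover (median ≈ 1.25 d), so
median production is several times higher than a flat prior on the
lifespan over the same support would give. Both readings appear in the
source literature; the rate parameterisation is used because division rate
is what the laboratory and model estimates actually constrain. Users
wanting the lifespan reading can pass custom `turnover_range` parameters.

For a flat prior on [a, b], E[S/τ] = S·ln(b/a)/(b−a); the Monte-Carlo
pipeline is tested against this closed form (and collapses exactly under
degenerate priors). Draws are matched across taxa within a station (one
draw per taxon per iteration), so share distributions are coherent, sum to
100% per draw, and the aragonite share (pteropods + heteropods) inherits a
proper CI. Summaries report 2.5/16/32/50/68/84/97.5 percentiles and a
density mode; 68% CIs are the 16–84 band.

Annualization multiplies by 365 and divides by a seasonal bias factor
(sampling-time conditions over annual mean): satellite PIC for
coccolithophores, satellite chlorophyll for foraminifera, and for the
gastropods a zooplankton-seasonality factor interpolated linearly in
latitude between the subtropical (22.75°N, 1.2) and subpolar (50.1°N, 2.0)
time-series anchors and clamped outside — latitude is the only covariate
the anchor series constrain. The full sample set is annualized, not just
its summary. In the synthetic bundle the PIC seasonal cycle stands in for
the chlorophyll proxy as well, since the generator emits a single
climatology.

## Skew-robust basin statistics

Basin compilations of biomass are heavily zero-inflated and right-skewed,
so means are poor descriptors. The pipeline keeps records in the upper
250 m (boundary inclusive), retains zeros, and removes 3σ outliers in a
single pass with moments computed zeros-included. (At very small n the 3σ
rule can never fire — the maximum |z| of an n-point sample is
(n−1)/√n — which the tests document.) Carbon converts to CaCO~3~ through
an uncertain PIC fraction fPIC = r/(1+r) with r uniform on the taxon's
PIC:POC range.

Densities use a zero-truncated Gaussian KDE: each kernel is renormalised by
its mass on [0, ∞), which up-weights observations near zero instead of
leaking density below the support, and the total density integrates to 1.
Bandwidth follows Silverman's rule on the untruncated sample; the mode is
located on a 2048-point grid spanning [0, max + 3h]; all-equal samples are
returned as point masses. Uncertainty combines bootstrap resampling of the
records with one joint (fPIC, τ) draw per iteration; iteration 1 always
uses the original sample, so `n_boot = 1` is a single-pass estimate.
Because stock and production are per-record scalar multiples of the
biomass values within an iteration and the truncated KDE is
scale-equivariant, their percentiles are computed by exact rescaling —
a threefold saving with no approximation.

## Global extrapolation

Station annual production is regressed on annual-mean satellite PIC by OLS
with intercept (the intercept absorbs subsurface production the satellite
cannot see). The fit is applied per ocean cell with predictions floored at
zero, and integrated with exact spherical band areas
R²·Δλ·(sin φ~top~ − sin φ~bot~), which sum to 4πR² by construction
(spherical Earth, R = 6371 km; ellipsoidal corrections are far below other
uncertainties). The annual field is the per-cell mean over months with
valid retrievals (winter gaps excluded, not zero-filled) and the ocean
mask is any-valid-retrieval. The low-PIC minimum estimate multiplies the
area fraction below 10 mg m^-3^ by low-PIC station rates, ignoring the
high-PIC remainder.

## What the synthetic generator does and does not emulate

The generator's defaults are the study conditions: five stations from
22.75°N to 50.1°N, total stocks rising from ~700 to ~4500 mg m^-2^, taxon
shares 79/14/6/1%, lognormal shell lengths per family, Gaussian-in-depth
coccolithophore profiles shoaling poleward, ~6.7% zero inflation and
lognormal skew in the biomass compilation (1793 records), an 87% low-PIC
ocean, a subpolar-bloom region covering the northern station, and a true
export efficiency of 0.2. Shell counts are drawn until the cumulative mass
meets the target, with the final individual kept probabilistically so the
expected realized stock equals the configured one; for heteropods (a few
shells per tow) single-shell granularity still dominates, which the truth
record reports honestly via separate configured and realized values.

Not emulated: real satellite spatial texture, geographic/seasonal sampling
bias of compilations, taxonomic misidentification, net avoidance or mesh
selectivity, and day/night tow differences. Passing recovery tests
therefore demonstrate the correctness of the accounting, not the field
accuracy of the constants.

## Numerical choices

* All masses are carried in mg CaCO~3~ internally; molar conversions
  (M(CaCO~3~) = 100.09, M(C) = 12.011 g mol^-1^) happen only at reporting
  boundaries.
* No intermediate rounding anywhere in the conversion chain.
* Every stochastic stage draws from a stream keyed by (seed, stage name),
  so adding a stage never perturbs another stage's draws, and all outputs
  are bit-reproducible given (inputs, config, seed).
* Test and acceptance problem sizes: 10^5^–10^6^ draws for closed-form
  convergence checks, 200 seeded repetitions for coverage calibration,
  2° climatology grids, 120–200 bootstrap iterations on ~1700-record
  compilations — sizes at which Monte-Carlo error is well below the
  asserted tolerances.

## A worked example

```{r example, eval = FALSE}
cfg <- synth_config(seed = 1)
dir <- tempfile()
simulate_bundle(cfg, dir)
res <- run_pipeline(dir, file.path(dir, "out"), n_draws = 4000, seed = 1,
                    cfg = cfg)
res$comparison            # production vs trap flux, ~20% exported
res$shares[["5"]]$summary # per-taxon production shares at the subpolar station
res$global$total_pg_c_yr  # area-weighted global production
```

## Known limitations

* The steady-state assumption ignores time lags between production and
  export; the 72-h floating-trap comparison is a snapshot by design.
* The zooplankton seasonal-bias factor corrects the seasonal trend only,
  not interannual variability, and assumes temperature-independent growth.
* The coccolithophore turnover prior choice (rate vs lifespan) moves
  absolute production by a factor of a few; relative comparisons (shares,
  export efficiency, residence times) are far less sensitive.
* The global regression rests on few stations and is driven by the
  high-PIC subpolar end member; its standard error should be read
  accordingly.
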