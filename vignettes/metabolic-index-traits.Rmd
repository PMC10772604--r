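---
title: "Diagnosing active hypoxia tolerance traits from biogeography: models and methods"
author: "aerotraits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Diagnosing active hypoxia tolerance traits from biogeography}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

Marine ectotherms need ambient O~2~ pressure sufficient to fuel their
metabolism, and the minimum viable pO~2~ rises with activity level and
varies with temperature. `aerotraits` works with the Metabolic Index

$$\Phi(p\mathrm{O}_2, T) \;=\; \frac{A_\mathrm{eco}\, p\mathrm{O}_2}
   {f(E(T),\, T)},
\qquad
f(E, T) = \exp\!\left[-\frac{E}{k_B}\left(\frac{1}{T_K} -
   \frac{1}{T_{\mathrm{ref},K}}\right)\right],$$

the ratio of ambient O~2~ supply potential to the demand of sustained
ecological activity. $\Phi \ge 1$ marks metabolically viable water and the
temperature-dependent lower threshold is
$p\mathrm{O}_2^{act}(T) = f(E(T), T) / A_\mathrm{eco}$. Three traits define
a species:

* `A_eco` (atm^-1^) — active hypoxia tolerance at the reference
  temperature (15 °C). Its reciprocal is the minimum viable pO~2~ at
  15 °C. `A_eco` relates to resting physiology through
  `A_eco = A_o / Phi_crit = 1/(V_h Phi_crit) = alpha_S/(alpha_D Phi_crit)`,
  where `Phi_crit` is the sustained-to-resting metabolic rate ratio.
* `E_eco_ref` (eV) — the effective activation energy of the threshold at
  15 °C. It decomposes as `E_eco = E_d − E_s + E_phicrit`: demand minus
  supply activation energies plus the temperature sensitivity of
  `Phi_crit` itself.
* `dEdT` (eV/°C) — a linear temperature dependence of the effective
  activation energy, `E(T) = E_eco_ref + dEdT (T − 15)`, a one-parameter
  stand-in for the multi-step nature of organismal O~2~ supply (diffusion
  dominating in warm water, ventilation/circulation in cold water).

Because biogeographic fitting cannot separate resting tolerance `A_o` from
the activity multiplier `Phi_crit`, the index implemented here is
normalised by `Phi_crit`: $\Phi = 1$ *is* the active threshold, and all
`Phi_max` quantities returned by the package are `Phi_max/Phi_crit`
ratios. Temperatures are °C everywhere at the interface and converted to
Kelvin only inside `arrhenius_factor()`; `k_B` is fixed at
8.617333262e-5 eV/K.

## Trait diagnosis by F1 maximisation

`build_occupancy()` snaps occurrence records to grid cells (half-open
lon/lat intervals, nearest depth level, month-resolved on monthly grids)
and confronts the occupied cells with a background of unoccupied ocean
cells from the species' depth range (± one level; a latitude envelope is
optional, the default background is global). `fit_traits()` then searches
the trait grid for the classifier `Phi >= 1` that best separates presence
from background, scored by the F1 statistic
`2TP/(2TP + FP + FN)` (zero when `TP = 0`).

**The fitting universe.** The separation is evaluated in *binned
temperature–pO~2~ state space*, not over raw geographic cells: a bin
(default 1 °C × 3 % of pO~2~, the latter log-spaced so resolution is
relative at every oxygen level) is a presence sample when at least one
occupied cell maps into it, a background sample when only unoccupied water
does. The reason is identifiability. The threshold is a curve in
(T, pO~2~); geographic cell counting weights each region of that plane by
the *volume of water* that maps there, which is enormous for the cold
oxygenated interior and tiny near the threshold. Measured on cell counts,
the F1 optimum is then dominated by far-field water and can sit far from
the generating traits; measured on state-space bins, the optimum tracks
the occupied lower envelope, which is the quantity the traits
parameterise. The raw-cell universe remains available
(`occupancy_opts(universe = "cells")`) and both share one code path, so
the construction can be revised in a single place. Confusion counts are
unweighted by default (each bin or cell counts once); water-volume
weighting sits behind `weighting = "volume"`.

**Search and plateau handling.** The default grid spans
`A_eco` 0.5–100 atm^-1^ (40 log-spaced points), `E_eco_ref` −1–2 eV
(step 0.05) and `dEdT` 0–0.12 eV/°C (step 0.01), covering the trait ranges
observed across marine ectotherms. The F1 surface is a step function:
moving one unit-weight sample across the threshold changes it by roughly
`1/(2 × presence weight)`. Grid points within twice that amount of the
maximum are statistically indistinguishable, and the raw argmax is an
arbitrary vertex of that flat plateau. The fit therefore reports the
plateau *centroid* (geometric mean `A_eco`, arithmetic mean `E_eco_ref`
and `dEdT`), refines the grid five-fold around it (one pass, ± one coarse
step per axis), and takes the refined plateau centroid. The procedure is
deterministic; a vertex tie-break (lowest `A_eco`, then `|E_eco_ref|`,
then `dEdT`) is retained internally for exact-tie ordering. A species with
fewer than 10 occupied cells is skipped, not fitted.

Reported alongside the traits: `T_C`/`T_W`, the 5th/95th percentiles of
occupied-cell temperature; `Phi_max`, the 95th percentile of the index
over occupied cells at the fitted traits; and the confusion counts behind
the final F1. All percentiles in the package use linear interpolation
between closest ranks (`stats::quantile` type 7).

## The synthetic study system

`make_ocean()` generates a zonal-mean climatology on a regular grid:
surface temperature falls from ~29 °C in the tropics to −1.8 °C at the
poles as `cos³(lat)` and decays with depth (e-folding 300 m) toward 2 °C;
pO~2~ is ~0.21 atm at the warm surface, supersaturates up to 5 % in cold
surface water, and at depth relaxes to a deep value that is high near the
poles (0.16 atm, young ventilated water) and low in the tropics
(0.06 atm, respired old water), with a Gaussian oxygen-minimum zone
(0.02 atm core at 350 m, low latitudes) that recovers only partially
below. Cell volumes come from spherical-shell geometry. Optional seeded
components add smooth longitudinal temperature anomalies and random land
columns; with defaults the grid is deterministic and zonally symmetric.
A sinusoidal, hemisphere-phased seasonal cycle is available via
`monthly = TRUE`. `o2conc_to_po2()` converts concentration climatologies
to pO~2~ with the Garcia–Gordon solubility fit at salinity 35 (open-ocean
mean).

`simulate_species()` draws occurrence records from the habitat
`1 ≤ Φ ≤ Phi_max` at known traits, sampling cells with probability
proportional to water volume and flipping each record to a uniformly
random non-habitat cell with probability `noise_rate` (a minimal
misdetection model). The default `Phi_max = Inf` makes species
lower-threshold-limited — they occupy all viable water, and their
*diagnosed* occupied `Phi_max` emerges from what the ocean offers above
the threshold, as it does for real species. A finite `Phi_max` restricts
occupancy to an index band; note that a species occupying a thin interior
band carries almost no information about its lower threshold (most viable
water is unoccupied), so band-limited truths are not recoverable by any
occupancy-based method and are not the generator's default.

`simulate_assemblage()` draws trait sets uniformly over the search ranges
(`A_eco` log-uniformly) and retains only *diagnosable* species: at least
50 habitat cells, and the lower threshold actually expressed in the
environment — habitable and sub-threshold water must coexist in at least
70 % of the inhabited 2 °C temperature bins, across a span of at least
8 °C reaching within 5 °C of the reference temperature. The last
conditions matter because `E_eco_ref` is defined *at* 15 °C: for a species
whose threshold is only expressed over a narrow or one-sided temperature
range, `E_eco_ref` is an extrapolation and `E` and `dEdT` are nearly
collinear (the Arrhenius exponent is `≈ 0.0147·(E·ΔT + dEdT·ΔT²)` around
the reference), so no estimator can pin them down individually.

**What passing tests show, and what they do not.** The generator emulates
the statistical structure the analysis assumes — occupancy filling a
Φ-defined region, volume-proportional sampling, label noise — on a smooth
zonally symmetric ocean. It does not emulate observation-effort bias,
spatial autocorrelation of records, mesoscale hydrographic structure, or
seasonal mismatch between records and climatology; parameter recovery
here is therefore a correctness check of the machinery, not a validation
of the method against real survey data. Even under these favourable
conditions, recovery of `E_eco_ref` to ±0.1 eV succeeds for roughly
three-quarters of uniformly drawn diagnosable species (the remainder are
high-|E| species whose occupied range sits to one side of the reference
temperature); `A_eco` to ±15 % succeeds for ~90 % and the median `dEdT`
error is well under 0.01 eV/°C. This is an honest picture of the
identifiability of the three-parameter threshold from 500 noisy records.

## Downstream diagnostics

* `habitat_volume()` / `habitat_volume_grid()` — water volume with
  `1 ≤ Φ ≤ Phi_max` per depth band (defaults 0–100 m and 100–1000 m),
  over an `A × E` trait grid at fixed `dEdT = 0.025` eV/°C and
  `Phi_max = 1.4`, the median occupied headroom. Monthly grids average
  monthly habitable volumes (an intersection/union variant was considered
  and rejected as harder to interpret; the average is what a
  climatological mean habitat means).
* `edge_sensitivities()` — `E_eco` evaluated at `T_W` and `T_C`; the
  difference is exactly `dEdT (T_W − T_C)`. Both the mean of per-species
  differences and the difference of means are reported by the analysis
  scripts, since the two summaries differ in general.
* `phi_max_ratio()` — occupied 95th-percentile Φ, i.e. `Phi_max/Phi_crit`
  under the normalisation above.
* `e_phicrit()` — `E_eco − E_o` at the species level;
  `e_phicrit_from_fas()` fits the Arrhenius slope of laboratory factorial
  aerobic scope measured at several temperatures.
* `ks_two_sample()` — the exact two-sample Kolmogorov–Smirnov statistic
  with the asymptotic p-value under Stephens' effective-sample-size
  correction (cross-checked against `stats::ks.test`, whose asymptotic
  variant omits the finite-n correction terms).

## Phylogenetic signal

Trees without divergence times receive Grafen branch lengths: node height
= (descendant tips − 1), normalised by (total tips − 1) and raised to
ρ = 0.4, the exponent found to best explain measured resting hypoxia
tolerance across fishes; polytomies are handled natively. `pagel_lambda()`
estimates Pagel's λ by profile maximum likelihood — for each λ the root
mean and rate σ² have closed-form GLS estimates under the Gaussian model
with the λ-transformed shared-path-length covariance — using bounded
scalar optimisation on [0, 1] with both boundaries checked explicitly.
The likelihood is evaluated through a dense Cholesky factorisation with a
relative conditioning guard of 1e−12; at the tree sizes this package
targets (hundreds of tips) the dense solve is simpler than and as fast as
a pruning recursion, which is why the linear-time variant was not
implemented. The likelihood-ratio test against λ = 0 reports the
χ²(1) p-value halved at the boundary (the null pins λ at the edge of its
range), alongside the plain χ²(1) value.

## Numerical and interface choices

* Half-open cell intervals `[edge, edge)` for occurrence snapping;
  latitude 90° and the date line clamp/wrap into the edge cells.
  Records without depth default to the surface level (flag-controlled;
  `"drop"` available) and records without a month match the annual mean.
* The plain-text grid format (JSON header + CSV fields with doubles
  rendered to 17 significant digits) round-trips bit-identically, which
  the pipeline-determinism tests rely on.
* All generators are pure functions of their parameters and a seed; the
  caller's RNG state is saved and restored around every draw.
* Worked problem sizes: the bundled analyses use a 2° × 12-level ocean,
  20–50 species and 500 records per species; at these sizes a full
  assemblage fit runs in well under a minute on one core.

## Known limitations

`E_eco_ref` for species occupying only water far from 15 °C is an
extrapolated quantity with the collinearity caveat above. The background
domain definition (depth-padded, optionally latitude-banded) is a stated
convention, not an inference; far-field true negatives do not affect F1
but the false-positive universe is part of the model. The synthetic ocean
is a smooth caricature of a climatology, and the misdetection model flips
labels uniformly — structured biases (effort, taxonomy, bathymetric
clustering) are out of scope.
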