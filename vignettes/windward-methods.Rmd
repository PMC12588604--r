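---
title: "Methods: counterfactual analysis of plateau-uplift effects on bird migration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: counterfactual analysis of plateau-uplift effects on bird migration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(windward)
```

# The analysis in one paragraph

The package asks how the uplift of the Qinghai-Tibet Plateau — through the
orographic barrier itself and through the Asian monsoon system it generates
— reshaped bird migration. It does so counterfactually: weekly species
distributions are reconstructed from checklist-style occurrence data with an
adaptive spatiotemporal ensemble model; a presence–background niche model
captures the species–environment correlation; that correlation is projected,
unchanged, onto a simulated pre-uplift environment (elevation capped at
300 m, no monsoon); and migratory directions — azimuths between adjacent
route nodes — are regressed on standardised environmental drivers (wind
cost, vegetation, temperature, precipitation, elevation) under both worlds.
The load-bearing assumption is **niche conservatism**: a species keeps its
environmental response across scenarios, so "same coefficients, different
environment" is a meaningful counterfactual. Nothing in the package tests
that assumption; it is encoded exactly as stated and nowhere else.

# The synthetic world

Every stage runs against a seeded synthetic world
(`generate_environment()`, `generate_species_truth()`,
`generate_checklists()`, `generate_tracks()`); all generators are pure
functions of (parameters, seed).

**What the generator emulates.** Two scenario stacks on a configurable
lat–lon grid (default ~1.9° × 2.5°, the atmospheric-model resolution the
real analysis used; tests run a 20 × 30-cell grid over 0–60°N, 60–140°E):

* a plateau block (75–105°E, 28–38°N) at ≥ 4000 m in the modern scenario,
  elevation capped at 300 m in the pre-uplift counterfactual;
* temperature falling with latitude and with elevation (lapse rate 6.5 °C/km)
  with a modest seasonal cycle (amplitude 2 + 0.12·lat °C — deliberately
  maritime, see below);
* monsoon winds over the sector 64–120°E / 5–30°N that reverse between
  winter (northeasterly) and summer (southwesterly) in the modern scenario
  only; the counterfactual keeps zonal background winds;
* monsoon rains whose wet core slides zonally through the year (summer core
  105°E, winter core 70°E, Gaussian width 12°), plus orographic
  precipitation over modern relief; the counterfactual has a smooth,
  seasonally constant precipitation field;
* vegetation fraction, a 10-class land-cover legend, and a 23-composite
  NDVI annual cycle derived deterministically from climate and terrain.

**Why these numbers.** The world is *constructed* so that the modern
monsoon rewards east–west movement: species' precipitation optima are
anchored to the wet end of the weekly precipitation field (90th–97th
percentile) with narrow breadths (8–15 % of range) and broad temperature
tolerances (4–7 °C), so in the modern scenario the prime habitat is the
migrating rain belt (zonal displacement ~2500 km/season) while in the
counterfactual, with no moving rain belt, only the weak temperature cycle
moves habitat (meridional, a few hundred km). This is the stated world of
the analysis — the claim under test is that the *pipeline* recovers the
direction contrast from data, not that the contrast exists. These
parameters were fixed while designing the world, by inspecting truth
centroid tracks under both scenarios, before any acceptance statistic was
computed.

**What the generator does not emulate, hence what a green test does not
establish:** atmospheric or ocean physics (no claim of reproducing any
earth-system model's fields), real species' niches, observation-process
subtleties beyond hotspot clustering and skill heterogeneity (no taxonomic
confusion, no shared-checklist duplication), and spatial autocorrelation of
detection errors. Passing tests establish that the algorithms implement
their contracts and that the inference machinery recovers known synthetic
truth — not that the biological conclusions hold for real data.

Checklists deliberately include QC-violating records (distances > 3 km,
durations outside (5, 300) min, incomplete flags) so the filters are
exercised; observer skill is a long-tailed log-normal latent with detection
probability monotone in the skill percentile.

# Stage-by-stage notes and numerical choices

## Checklist QC

* Duration bounds are strict (`5 < d < 300` min), reading "longer than …
  and shorter than …" literally.
* The expertise percentile is the midrank empirical CDF
  `100·(#{<} + ½·#{=})/n`: ties share one percentile, an all-tied population
  sits at 50 (retained), and the lowest of 40 distinct counts sits at 1.25,
  below the 2.5 cut. Ties at the cut are retained (`≥ 2.5`).
* Hex indexing: no H3 binding exists for R in this stack, so a documented
  fallback is used — a pointy-top axial hex lattice on the sinusoidal
  equal-area projection, level-7 cell area 5.161293 km², aperture-7 area
  scaling across levels. Cells are deterministic and non-overlapping (the
  contract downstream code uses); exact parent–child nesting is *not* a
  property of this lattice, so `hex_parent()` is defined as re-indexing the
  child centroid and holds at typical points only.
* Subsampling orders records canonically (by key, then checklist id) before
  the seeded uniform draw, so the retained set is independent of input row
  order.

## Feature engineering (106 columns)

Families 6 + 2 + 8 + 19 + 65 + 6. Choices where the published decomposition
is silent:

* Protocol is one-hot over {Traveling, Stationary} (2 columns), which
  reconciles the 5-item effort list with the printed count of 6.
* The 65 land-cover columns are a schema-compatibility convention: 10
  canonical classes × 6 per-class metrics (percentage cover, patch density,
  largest patch index, edge density, mean and sd of patch size;
  4-connectivity, densities per km² of buffer) + entropy of class
  composition (nats) + 4 buffer-level metrics (total patch density, overall
  largest patch index, overall edge density, overall mean patch size).
  Per-class edge density counts internal class–other cell adjacencies, so a
  homogeneous buffer has edge density 0.
* Bioclim quarters are all 12 rolling 3-month windows with December–January
  wraparound; BIO4 = 100·sd of monthly means (sample sd, n−1); monthly
  "max/min temperature" are the within-month extremes of the daily series;
  BIO15 = 100·sd/mean of monthly precipitation, defined as 0 when the mean
  is 0; BIO3 defined as 0 when BIO7 = 0.
* Aspect is the downslope direction clockwise from north
  (northness = cos, eastness = sin); flat cells get 0 for both; slope is in
  radians.
* The NDVI smoother is implemented exactly as specified — 30 cubic
  B-splines, second-difference penalty, GCV-chosen λ over a log grid —
  rather than via `mgcv`, because 30 basis functions exceed the ~23
  observations of a 16-day cadence (mgcv refuses k > n; penalised
  least-squares does not). The basis uses equally spaced knots extended
  three steps past each boundary, so the penalty's null space is exactly
  the linear functions and a linear series yields its slope as the
  derivative features. The smoother is non-cyclic in day-of-year (the
  cyclicity of the original is unstated); extrapolation beyond the observed
  DOY range is penalty-driven and effectively linear.
* Fine-scale (1 km) DEM and land-cover patches are generated on demand
  around each point from the coarse fields plus a hash-based (RNG-state
  free) roughness term, so the same point always yields the same patch
  without storing a global fine raster.

## Stixel ensemble

* The QuadTree splits on space only; time is handled by the cyclic 50-day
  windows (step 20, 19 windows, every DOY covered by ≥ 2). A node splits
  iff its side exceeds 25°, or halving keeps it ≥ 5° and it holds ≥ 50
  points; only leaves with ≥ 50 training checklists carry fitted models. A
  consequence worth knowing at desk scale: fitted stixels exist only where
  the data are dense enough (≥ 50 checklists per ~5° cell per window), so
  sparse synthetic runs are mostly masked — exactly how the coverage mask
  is meant to behave.
* "More than seven ensembles" is read literally: cells with coverage ≤ 7
  are masked (configurable).
* Folds are aggregated by the **median** (robust to a wild fold; the
  original's statistic is unstated).
* A query takes, within each fold, the window whose centre is nearest its
  DOY (cyclic distance, ties to the earlier window).
* Prediction-time effort covariates are standardised to a canonical survey
  (Stationary, 60 min, 0 km, 1 observer, training-median expertise, 07:00,
  the queried week's mid-DOY) so cells are comparable.
* The default hurdle base learner is squared-loss gradient boosting on a
  compiled CART kernel (no gradient-boosting package is available in this
  stack); any `fit/predict` pair can be plugged in, and the stratified-mean
  learner makes the single-fold ensemble equal a group-by mean — the oracle
  the tests use. A stixel whose counts are all zero keeps a classifier-only
  model predicting zero abundance.
* The quantile filter masks cells with abundance strictly below the
  per-species-week 0.1 quantile of unmasked cells; constant fields lose
  nothing, and an all-masked input is returned unchanged with a warning.

## Niche model

* "Default settings" of the original tool are reinterpreted for a
  from-scratch implementation as linear + quadratic features per layer
  (scaled to the training range), L1 penalties following the
  regularisation-by-sample-size schedule `r(n)·s_j/√n` (r interpolating
  1.0 → 0.6 → 0.5 over 10 → 30 → 100 presences), logistic output, and
  clamping to training ranges at projection time. Hinge and product
  features are omitted (documented simplification).
* The background carries a fixed total weight of 100× the presence count
  (per-point weight `100·n_pres/n_bg`), which makes the fit invariant to
  enlarging a background sample with the same empirical distribution.
* The published iteration cap (1000) counts the original sequential
  algorithm's steps; it does not map 1:1 to the coordinate-descent passes
  of the lasso path used here, so `maxit` defaults to 1e5 passes (capping
  at 1000 truncates the path). Non-convergence is flagged, never silent.
* Degenerate inputs: constant layers get zero coefficients with a warning;
  an all-constant environment yields the uniform model.

## Wind connectivity

* The movement-cost formula is made explicit (the original defers to a
  package default): for the edge o→t with bearing b and wind (speed ws,
  direction θ, blow-toward convention, u = 1, v = 0 → 90°) at o, the cost is
  `d(o,t) · exp(−ws·cos(θ−b)/s₀)` with s₀ = 5 m/s — strictly positive,
  decreasing in tailwind, pure distance in calm air.
* Connectivity is sampled-pair least-cost-path betweenness (all-pairs mode
  for grids ≤ 2500 cells); the reversal into the wind-cost layer is affine
  (`max − x`), exactly inverting rank order while preserving scale for
  standardised regression.
* Tie-breaking caveat: with exactly tied path costs (calm air on a regular
  grid) the single returned least-cost path is an arbitrary representative,
  so per-cell connectivity is only symmetric up to tie-breaking; the
  distance matrix itself is exactly symmetric and is what the tests check.
* Monthly layers aggregate to seasonal/annual layers by the mean of monthly
  connectivities (reversal applied after averaging).

## Migration geometry

* Great-circle math on a sphere of radius 6371.0088 km; bearings are
  initial azimuths wrapped to [0, 360); identical or antipodal endpoints
  are rejected (bearing undefined).
* Breeding/wintering delineation from weekly centroid tracks is a
  documented stand-in (the original's rule is unstated): cyclic runs of
  weeks with step displacement < 100 km/week; the two longest runs are the
  stationary periods, the one overlapping weeks 22–35 is breeding; fewer
  than two runs flags the species non-migratory.
* Stage (west < 73°E ≤ central < 105°E ≤ east) is taken at the segment
  midpoint longitude (endpoint vs midpoint is unstated); direction classes
  use ±45° sectors about north/south, with the 45° boundary assigned
  latitudinal.

## Direction drivers

* Drivers are endpoint-cell means (along-route averaging unstated);
  standardisation is applied within each model's data subset, and
  zero-variance columns are a hard error.
* The regression treats azimuth in degrees as a linear response, as the
  original does. That is statistically delicate for angles; it is valid
  when the azimuths of a subset stay within one half-circle, which the
  synthetic world's stated conditions satisfy. For other uses,
  `direction_rose()` and the circular mean are provided, and users can
  regress sine/cosine components by passing a transformed response — the
  linear treatment is retained because it is what the analysis specifies.
* The response is left on its natural scale when `fit_bayes()` is called
  directly (so a true coefficient of 0.5 is recovered as 0.5); prior scales
  (β ~ N(0,1), σ, τ ~ HalfNormal(1), α ~ N(0,10)) assume roughly
  unit-scale data and are arguments.
* **Sampler.** No NUTS implementation is available in this stack, and the
  model — Gaussian linear regression with optional species intercepts
  αₛ ~ N(α, τ) — is conditionally conjugate, so the posterior is sampled
  *exactly* by a partially collapsed Gibbs sampler: conjugate draws for β,
  α and the species effects; slice updates for σ and τ; α and τ updated
  with the species effects integrated out (each species contributes
  r̄ₛ ~ N(α, τ² + σ²/nₛ)), which removes the funnel that cripples naive
  Gibbs when τ → 0. Chain counts match the published protocol
  (4 × (3000 + 3000)); convergence is *enforced as a flag* — max
  rank-normalised split-Rhat < 1.03 and min bulk ESS > 400 — never
  silently.
* Diagnostics are the standard rank-normalised split-chain definitions
  (inverse-normal transform of fractional ranks; Geyer
  initial-monotone-positive-sequence truncation of the autocorrelation sum,
  FFT autocovariances), cross-checked against coda on autocorrelated
  chains in the test suite.
* The random forest is bagged CART with OOB permutation importance;
  counterfactual tables are standardised with the **training** constants
  (asserted by a leakage-guard test), and predicted azimuths are wrapped to
  [0, 360).

## Pipeline

A single YAML config carries every published constant as a named key
(3 km; 5/300 min; 2.5 %; 12 hour bins; level-7 hexes; 25°/5°/50; 10 folds;
50/20 DOY; coverage > 7; 0.1 quantile; 20 replicates; 75 %; 73°/105°E;
4 × (3000 + 3000); 1.03; 400). Unknown keys are rejected before any stage
runs. The run manifest records per-stage status and MD5 checksums of every
artifact; deterministic stages rerun with the same config and seeds produce
identical checksums. At demo scale the stixel surfaces are heavily masked
(see above), so the niche stage falls back to raw detection locations when
fewer than 15 unmasked cells survive — the pipeline supports both sources,
and the fallback is logged.

# Known limitations

* The fallback hex lattice is not H3; only the deterministic-partition
  contract is preserved.
* The linear treatment of azimuth is inherited from the analysis and is
  only sound for half-circle-concentrated subsets.
* Single-path betweenness under exact cost ties is representative, not
  exhaustive.
* Desk-scale data densities leave most stixel cells masked; the ensemble's
  behaviour at realistic densities is exercised only on the dense toy
  blocks in the test suite.
* The counterfactual logic inherits niche conservatism axiomatically; no
  empirical result in this package bears on whether it is true.
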