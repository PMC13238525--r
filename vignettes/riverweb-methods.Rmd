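---
title: "Methods: inferring and mapping river food webs from eDNA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: inferring and mapping river food webs from eDNA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`riverweb` couples two inference problems that are usually treated
separately: reconstructing *who eats whom* from community-wide eDNA
abundance profiles, and reconstructing *where each taxon lives* from eDNA
signals that rivers physically transport away from their sources. Their
combination yields a spatially continuous map of food-web structure over
an entire drainage network from a few dozen water samples. This vignette
explains each model, the parameters that matter, the numerical choices,
and what the synthetic scenarios do and do not establish.

## 1. The river network model

A drainage network is a tree of *reaches* (the edges; junctions are
implicit). Each reach carries hydraulic attributes: length, width, slope,
elevation, and the direct source area that drains laterally into it.
Exactly one reach, the outlet, has no downstream neighbour; the downstream
relation must be acyclic, and the constructor (`as_reach_network()`)
verifies this by a breadth-first sweep from the outlet.

Distance to the outlet is measured from a reach's *upstream* end, so every
reach contributes its own length and the distance strictly decreases at
every downstream step. This makes the distance axis unambiguous and
monotone, which is all the gradient analyses require.

## 2. Hydrology

Remote sensing gives channel width, not discharge. We invert the
downstream hydraulic-geometry relation `W = a_w * Q^b_w` (defaults
`a_w = 7.2`, `b_w = 0.5`, both dimensionless, configurable) to get a local
width-based discharge estimate, optionally modulated by channel slope
through an exponent `gamma` (default 0). Because widths are noisy, routed
discharge takes the maximum of the local estimate and the summed inflow
from immediately upstream — discharge never decreases downstream, which
the dilution logic requires. A pure summation mode exists for exact
mass-balance checks. Depth follows `d = a_d * Q^b_d` (defaults 0.27,
0.39) and mean advection velocity is `v = Q / (W d)`.

## 3. eDNA transport: forward model

Each reach emits eDNA at rate `p_i * A_i` (production per area times
source area). Emitted mass is advected downstream and decays
exponentially with travel time, with a single decay time constant `tau`
(seconds) shared across taxa; fluxes add at confluences, and the
concentration at reach `j` is the accumulated decayed flux divided by the
discharge `Q_j`:

`C_j = (1 / Q_j) * sum over upstream reaches i of p_i A_i exp(-t_ij / tau)`

Travel time `t_ij` sums `length / velocity` over the path from `i` to `j`
inclusive of both endpoints: mass shed in a reach is treated as traversing
that reach's full length. We considered a half-length convention for the
source reach; the full-length convention was chosen because it makes the
self-to-self travel time of a reach equal its own transit time and keeps
the hand-checkable confluence example exact. The sweep is a single
upstream-to-downstream fold (`F_j = D_j (e_j + sum of upstream F)`),
linear in the number of reaches and in the production vector — properties
the tests exploit (superposition, mass balance at `tau -> inf` to 1e-9
relative).

## 4. Inverse calibration

Observed site values (reads) are fitted by minimising the sum of squared
differences between `log(pred + 1)` and `log(obs + 1)` over log `tau` and
a per-taxon log production scale. Read counts span orders of magnitude,
so a log loss with a one-count pseudocount is the natural scale. The
forward map is linear in production, so at any fixed `tau` the per-taxon
scale is a smooth one-dimensional subproblem; we profile it out with
`optimize()` and run a multi-start bounded quasi-Newton (L-BFGS-B) search
over log `tau` only (10 starts by default, seeded, bounds 60 s to 1e7 s).
This is exactly the stated joint minimisation, solved block-wise; it cuts
each objective evaluation to one network sweep.

Identifiability is reported, not hidden: with fewer than 5 sites (or a
single-reach network) `tau` and production trade off freely and the fit
is flagged `degenerate`; all-zero taxa are skipped with a warning.
Leave-one-out cross-validation refits without each site and reports the
Pearson correlation between held-out log predictions and observations.
Discharge uncertainty can be propagated by log-normal Monte-Carlo
perturbation of routed discharge (`perturb_discharge()`), an
interpretation of verbal methods rather than a stated algorithm.

Under the generator's default observation conditions (40 sites,
log-normal noise sigma = 0.3, production proportional to abundance), the
acceptance suite verifies a median relative error of `tau` at or below
25% over 20 seeded replicates, and recovery within 1% on noise-free data.

## 5. Empirical dynamic modeling and link inference

Trophic links are inferred by convergent cross mapping (CCM) on
*spatially ordered* abundance profiles: sites are sorted upstream to
outlet by flow distance, and each taxon's standardized profile is treated
as an ordered series. The ordering axis is a documented design choice —
flow order is the only ecologically meaningful one-dimensional axis for a
single-campaign spatial survey — and CCM results must be read as
detecting spatially propagated dynamical coupling, not temporal causality.

The core is classical: delay embedding (`E` chosen per source taxon by
leave-one-out simplex self-prediction over `E = 1..E_max`, lag 1),
simplex projection with `E + 1` nearest neighbours weighted by
`exp(-d/d_1)` (exact matches take all weight), and cross-map skill `rho`
as the Pearson correlation between predictions and concurrent values of
the putative driver. Skill is evaluated over random libraries drawn
without replacement at an increasing grid of library sizes (seeded;
implemented in C++ since the pairwise scan is the pipeline's hot loop,
and verified against an exhaustive pure-R neighbour-search oracle to
1e-12).

A direction is *convergent* when skill grows by more than 0.1 from the
smallest to the largest library and exceeds 0.2 at the largest; skill
already above 0.9 at the smallest library counts as converged, since
ceiling-level skill has no room to grow. Significance comes from
cyclic-shift surrogates of the target series (`p = (1 + #{rho_null >=
rho_obs}) / (1 + n_surrogates)`). A known blind spot, observed on the
classic bidirectionally coupled logistic benchmark: when the target
dynamics are phase-locked and near-periodic, half of all cyclic shifts
preserve the phase alignment and the null concentrates at the observed
skill, so weak couplings that express themselves purely through
phase-locking cannot be separated from the null by any shift-based
surrogate. We therefore report pair-level significance (Bonferroni over
the two orderings) when both directions are of interest, and document
that the weak direction of the benchmark is detected by convergence, not
by the surrogate test.

Only cross-trophic-group ordered pairs are tested (plus fish-fish pairs
across feeding guilds, switchable), both orderings per pair; a pair
yields one link when either ordering is convergent and significant at
`alpha = 0.05`. Orientation is imposed by trophic rank (fish >
zooplankton > algae > bacteria; fish-fish by guild rank), stored
consumer -> resource. Surrogates are computed only for convergent
directions, since non-convergent ones can never be retained.

## 6. Food-web structure

The occupancy filter retains taxa detected at strictly more than half of
the sites (the standard guard against sporadic false-positive eDNA
detections) and requires at least two surviving trophic groups. The
metaweb is the deduplicated union of inferred links over all retained
taxa; isolated taxa remain nodes and count in S. Metrics: connectivity
L, link density L/S, connectance L/S^2, prey-averaged trophic level
(TL_i = 1 for nodes with no resources, else 1 + mean TL of resources,
solved as the linear system `(I - W) TL = 1` so intra-trophic cycles are
handled; closed consumer cycles with no basal exit are an error naming
the component), omnivory (population SD of a consumer's resource TLs,
zero for single-resource consumers; community omnivory is the mean over
consumers), and trophic length, which we define as the maximum
prey-averaged trophic level — the standard food-chain-length surrogate,
isolated in one place because the term is used loosely in the literature.
Basal status is derived from link structure, not group labels, so metrics
stay well-defined on arbitrary inferred webs. Local (per-site or
per-reach) webs are induced subgraphs on present taxa; webs with fewer
than two nodes are flagged degenerate and carry missing metrics rather
than fabricated zeros.

## 7. Spatial mapping and gradient statistics

`map_metrics()` evaluates the local web of every reach under the
transport-predicted presence field (presence = predicted concentration at
or above a per-taxon threshold; the default threshold is the smallest
concentration predicted at any site where the taxon was actually
detected — the weakest demonstrably detectable signal). Gradients are
Gaussian identity-link GLMs (ordinary least squares) of each metric on
distance to the outlet plus Pearson correlations; degenerate reaches are
excluded, never zero-filled. Pressure contrasts split reaches at the
median human footprint and use two-sided Mann-Whitney tests; the median
split is our choice where the grouping was not stated. Environmental
relationships use tie-corrected Spearman correlations with pairwise
deletion.

## 8. PLS path modeling

The climate -> human activity -> diversity -> complexity pathway is
fitted by partial least squares path modeling, implemented in-package
(Lohmoeller's alternating algorithm, reflective Mode A measurement,
centroid inner scheme by default, tolerance 1e-7 on outer weights, 300
iterations). Each latent is oriented to correlate positively with its
first indicator. Path coefficients are OLS regressions among unit-
variance latent scores; loadings are indicator-score correlations;
GOF = sqrt(mean communality x mean R2 over endogenous latents).
Indicators with |loading| < 0.7 are pruned iteratively; VIFs
(1/(1 - R2) of each predictor on its co-predictors) are screened at 5.
Significance is by seeded case-resampling bootstrap (percentile
intervals; two-sided p from the bootstrap mass on the far side of zero) —
the standard choice where no procedure is stated. Indirect effects are
products of path coefficients summed over directed paths, computed from
powers of the (nilpotent) path matrix. With single-indicator blocks the
whole machinery reduces exactly to OLS path analysis, which the tests
verify against `lm()` to 1e-10.

## 9. Synthetic scenarios: what they emulate

The generator builds the full causal chain with known truth:

* **Network** — a random binary confluence tree (2n - 1 reaches for n
  headwaters); widths grow with accumulated headwater count via the same
  hydraulic-geometry relation the estimator inverts, slopes decay
  downstream, and each reach's direct source area defaults to its length
  times 400 m of lateral drainage, log-normally perturbed — a one-time
  realism choice, not a fitted quantity.
* **Covariates** — precipitation tracks elevation inside a stated range;
  the human footprint follows a chosen spatial pattern, clipped to its
  defined 0-50 scale.
* **Community** — Ricker dynamics per reach with a known signed
  interaction matrix (consumers gain from resources, resources lose to
  consumers; eligible pairs drawn at the stated density), growth rates in
  the mildly chaotic regime (r in 2.6-3.2), plus 2% downstream advective
  dispersal. Carrying capacity is suppressed by the human footprint in
  proportion to trophic rank, so pressure hits fish hardest — the
  mechanism that gives the two presets their opposite spatial gradients.
  The final snapshot across reaches is the "sites x taxa" table: a
  space-for-time design matching a single sampling campaign.
* **Observations** — production proportional to abundance, transport
  under a known `tau`, sites stratified by distance quartile, Poisson
  reads of `capture x concentration` after log-normal noise
  (sigma = 0.3).

Two presets bracket the contrast of a humid low-pressure basin against an
arid high-pressure one: `han_like` (1435 reaches, 77 taxa split
30/22/14/11 across fish/zooplankton/algae/bacteria, 44 sites,
precipitation near 1000 mm/yr, footprint increasing downstream) and
`wei_like` (931 reaches, 63 taxa split 26/14/14/9, 33 sites, ~300 mm/yr,
footprint decreasing downstream). Preset transport parameters
(`tau = 3600` s, capture 200 counts per concentration unit) were chosen,
once, to place the scenarios in the regime where eDNA signals are
spatially informative: decay long enough for detection, short enough
that downstream accumulation does not swamp local community structure.
Under these documented conditions the humid preset's food-web complexity
declines from upstream to the outlet and the arid preset's rises — the
qualitative contrast the pipeline is designed to resolve — and this is
asserted as a seeded regression test, not as a claim about any real
basin.

What the synthetic scenarios do **not** establish: recovery of real
trophic links (the generator's interactions are direct and pairwise;
real communities have indirect effects, environmental forcing shared
across taxa, and observation processes far richer than Poisson reads);
absolute eDNA decay rates (the generator's `tau` is a convenience
value inside the empirically reported range, not an estimate); and any
quantitative correspondence to a particular river system.

## 10. Problem sizes and numerical choices

The shipped tests run the full pipeline at the presets' native sizes
(~1435 and ~931 reaches, 77/63 taxa, 44/33 sites) with 30 random
libraries per size and 60 surrogates per convergent direction; the
module-level defaults are 100/100. CCM library grids start at `E + 4`
points and end at the embedding count. Calibration bounds `tau` to
[60 s, 1e7 s] and uses 6-10 seeded starts. Trophic levels use a dense
solve (webs here are small); an iterative Jacobi oracle cross-checks it.
All randomness flows through explicit integer seeds; rerunning a
pipeline configuration reproduces every numeric output byte-for-byte.

## 11. Known limitations

* CCM on spatial profiles detects propagated dynamical coupling along the
  flow axis; with ~40 ordered sites the embeddings are short, and weak
  couplings are detected mainly through convergence rather than surrogate
  significance.
* Cyclic-shift surrogates lose power against phase-locked periodic
  dynamics (Section 5).
* The transport model is steady-state, first-order, purely advective: no
  hyporheic exchange, resuspension, or within-day dynamics.
* A single `tau` is shared across taxa per run; taxon-specific decay is a
  configuration extension, not the default.
* Presence thresholds derived from detected sites inherit any detection
  biases of the observations; where a taxon was never detected, it is
  mapped absent everywhere.
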