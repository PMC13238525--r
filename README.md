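# riverweb

Rivers carry environmental DNA (eDNA) away from the organisms that shed
it, so a water sample taken at one point in a drainage network is a
blurred, transported image of the communities upstream. `riverweb` turns
a few dozen such samples into a spatially continuous map of food-web
structure over an entire river basin, for ecologists studying how climate
and human pressure reshape riverine ecosystems.

The package couples two inference engines behind a tidyverse-style
interface (data frames in, tibbles out):

* **Trophic-link inference by empirical dynamic modeling.** Sites are
  ordered upstream to outlet along the flow axis; each taxon's
  standardized abundance profile is delay-embedded (Takens
  reconstruction), and convergent cross mapping (CCM) tests every
  cross-trophic-group pair of taxa: if the attractor reconstructed from
  taxon x's profile can predict concurrent values of taxon y with skill
  ρ that *grows with library size*, y's dynamics force x's. Simplex
  projection uses the E+1 nearest neighbours with weights
  `exp(-d_i/d_1)`; retained pairs (convergent, cyclic-shift surrogate
  p ≤ α) become directed consumer → resource links oriented by trophic
  rank. The union over taxa is the basin metaweb, summarized by
  connectivity L, link density L/S, connectance L/S², prey-averaged
  trophic level (`TL_i = 1 + mean TL of i's resources`, solved as a
  linear system), omnivory (SD of a consumer's resource trophic levels),
  and trophic length (max TL).

* **An eDNA–hydrological transport model.** Each reach emits eDNA in
  proportion to production `p_i` and source area `A_i`; the signal is
  advected downstream, decays exponentially with travel time (time
  constant τ), and is diluted by discharge at confluences:

  `C_j = (1/Q_j) Σ_{i ∈ upstream(j)} p_i A_i exp(−t_ij / τ)`

  Discharge comes from remotely sensed widths via inverted hydraulic
  geometry (`W = a_w Q^{b_w}`), velocity from discharge and channel
  cross-section. τ and per-taxon production are calibrated against
  observed site reads by multi-start bounded quasi-Newton minimisation of
  a log-scale least-squares loss, validated by leave-one-out
  cross-validation. The calibrated model predicts per-reach presence for
  every taxon, hence a local food web — and its metrics — for every one
  of the ~10³ reaches of a basin.

Downstream of these, the package provides upstream→outlet gradient tests
(Gaussian GLM + Pearson), pressure contrasts at the median human
footprint (Mann–Whitney), Spearman environment–metric correlations, and
a partial least squares path model (Lohmöller algorithm; loading
pruning at 0.7, VIF screening at 5, GOF = √(mean communality × mean R²),
bootstrap significance) for the climate → human activity → diversity →
complexity pathway. A synthetic-scenario generator builds river
networks, multi-trophic Ricker communities with known interaction
matrices, and eDNA observations with known decay parameters, so every
stage is testable against ground truth.

## Worked example

The transport model on a hand-checkable Y-junction — two 1000 m
headwater reaches (velocity 1 m/s, unit mass flux each, discharge 1 m³/s)
meeting at a zero-length outlet carrying their combined discharge, with
τ = 1000 s:

```r
library(riverweb)

y <- as_reach_network(tibble::tibble(
  reach_id = c("A", "B", "C"), downstream_id = c("C", "C", NA),
  length_m = c(1000, 1000, 1e-9), width_m = 7.2, slope = 0,
  elevation_m = 0, source_area_m2 = 1))
h <- tibble::tibble(reach_id = c("A", "B", "C"),
                    discharge = c(1, 1, 2), velocity = 1)
forward_concentration(y, h, tau = 1000, production = matrix(c(1, 1, 0), ncol = 1))
#> # A tibble: 3 × 3
#>   reach_id taxon_id concentration
#>   <chr>    <chr>            <dbl>
#> 1 A        taxon1           0.368
#> 2 B        taxon1           0.368
#> 3 C        taxon1           0.368
```

Each headwater's unit flux decays by `exp(−1000 s / 1000 s)`; the outlet
receives `2e⁻¹` mass flux in 2 m³/s of water, so all three reaches sit at
`e⁻¹ ≈ 0.368` — dilution exactly offsets the doubled load.

CCM on the classic bidirectionally coupled logistic pair (x forces y with
strength 0.1) recovers the forcing from the forced variable's attractor:

```r
n <- 500; x <- y <- numeric(n); x[1] <- 0.4; y[1] <- 0.2
for (t in 1:(n - 1)) {
  x[t + 1] <- x[t] * (3.8 - 3.8 * x[t] - 0.02 * y[t])
  y[t + 1] <- y[t] * (3.5 - 3.5 * y[t] - 0.1 * x[t])
}
ccm(y[101:500], x[101:500], E = 2, seed = 1)
#> <ccm_result> E = 2  rho(L_max) = 0.918  convergent: TRUE
```

A complete run — synthetic arid-basin scenario, link inference, transport
calibration, and per-reach mapping — from one configuration:

```r
b <- run_pipeline(list(
  seed = 1,
  input = list(preset = "wei_like", preset_headwaters = 30),
  edm = list(n_samples = 10, n_surrogates = 30, E_max = 3,
             lib_sizes = c(8, 12, 16, 20, 25))))
b
#> <riverweb_run> metaweb S = 63 L = 183 | tau = 3540 s
dplyr::select(b$gradients, metric, slope, r, p)
#> # A tibble: 5 × 4
#>   metric                   slope       r      p
#> 1 L                  -0.960      -0.271  0.0378
#> 2 link_density       -0.00814    -0.255  0.0515
#> ...
```

The metaweb keeps all 63 simulated taxa with 183 inferred links, the
decay constant is recovered near its generating value (3540 s vs the
preset's 3600 s), and connectivity L declines with distance to the outlet
(slope −0.96 links/km, r = −0.27): in this high-pressure-upstream
scenario, food webs get richer toward the outlet. The `han_like` preset
(humid, pressure increasing downstream) shows the opposite trend —
`compare_basins()` tabulates the contrast.

Result objects have `tidy()`/`glance()` methods and `autoplot()`
(skill curves, calibration fits, food webs); `plot_gradient()` draws
metric–distance trends.

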