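# spatioepi

Spatial–temporal heterogeneity analysis of areal disease-incidence
panels: who gets sick where, whether that geography is clustered,
which factors explain it, and how those relationships drift over space
and time.

The package is written for epidemiologists and spatial analysts working
with long-format panels of administrative units observed yearly — an
age-standardized incidence outcome (per 10,000) plus continuous
covariates — together with a spatial contiguity structure (GAL neighbor
list or GeoJSON polygons). It implements the four analysis stages such
studies chain together, each testable end to end against synthetic
panels with known ground truth:

1. **Global spatial autocorrelation** — Moran's
   *I* = (N/S₀) Σᵢⱼ wᵢⱼ(xᵢ−x̄)(xⱼ−x̄) / Σᵢ(xᵢ−x̄)², with
   randomization-assumption z-scores (Z > 2.58 flags 99% clustering)
   and permutation inference, per year and per five-year window.
2. **Local hot spots** — the self-inclusive Getis-Ord Gi* statistic with
   90/95/99% hot/cold bins (|z| thresholds 1.645/1.960/2.576) and a
   persistence summary across windows.
3. **Stratified heterogeneity (GeoDetector)** — the q-statistic
   q = 1 − SSW/SST with noncentral-F significance, discretization search
   over equal-interval / geometric / Jenks natural-breaks / quantile
   binning, pairwise interaction classification (bilinear vs nonlinear
   enhancement, independence, weakening), and a ±10% perturbation
   sensitivity analysis judged against the 10% stability threshold.
4. **GTNNWR** — geographically and temporally weighted neural-network
   regression: a proximity network fuses spatial and temporal distances
   into spatiotemporal proximities, a weight network turns each point's
   proximity profile into per-coefficient weights wᵢ, and predictions
   ŷᵢ = Σₖ wᵢₖ βₖᴼᴸˢ xᵢₖ modulate a global least-squares fit, yielding
   coefficient surfaces βᵢₖ = wᵢₖ βₖᴼᴸˢ that vary over space and time.
   Trained with an NMSE loss, Adadelta, multistep learning-rate decay,
   dropout and batch normalization, under a 75/10/15 hold-out split
   (seed 48).

A synthetic-data module generates the study conditions: SAR random
fields with tunable clustering, covariates whose stratification explains
an exactly requested variance share, and 48-unit × 30-year lattice
panels with known spatiotemporally varying coefficients.

## Worked example

```r
library(spatioepi)

# a 48-unit lattice field with strong spatial autocorrelation
W <- make_grid_weights(6, 8, "rook")
f <- simulate_sar_field(W, rho = 0.8, sigma = 1, seed = 7)
global_morans_i(f, W)
#> Moran's I = 0.5370  (E[I] = -0.0213, z = 5.1624, p = 1.22e-07,
#>   randomization)  [significant clustering]

# exact closed loop between the generator and the factor detector
s <- simulate_stratified_covariate(rep(c("a","b","c"), each = 16),
                                   target_q = 0.7, seed = 3)
q_statistic(as.numeric(s$field), s$strata)
#> q = 0.7000 (L = 3, N = 48, ...)

# spatiotemporal regression on a nonstationary 1440-record panel
bm <- gtnnwr_benchmark()   # ~6 min on one CPU
bm$metrics$validation
#> R2 0.8562 | RMSE 0.5064 | ...
bm$metrics$test$rmse       # 0.5215 — beats the global OLS baseline
bm$metrics$ols_test$rmse   # 0.5578
bm$beta1_cor               # 0.918: fitted vs true coefficient surface
```

The Moran line says the simulated field clusters far beyond chance (I
well above its null expectation −1/47, z > 2.58). The q line shows the
detector returning exactly the variance share the generator planted.
The benchmark lines show the weighted regression explaining essentially
all explainable variance (the noise floor puts the ceiling near
R² 0.86), predicting held-out records better than a global linear fit,
and recovering the planted spatially/temporally varying coefficient
surface with r = 0.92.

## Analysis workflow

The `analysis/` scripts run the full study sequence on synthetic inputs
and write tables under `results/`:

```sh
Rscript analysis/01_simulate.R            # panel CSV + GAL weights + truth
Rscript analysis/02_spatial_clustering.R  # Moran series, Gi* bins, persistence
Rscript analysis/03_geodetector.R         # factor q, interactions, sensitivity
Rscript analysis/04_gtnnwr.R              # regression metrics + coefficients
Rscript analysis/05_report.R              # one-call pipeline, full bundle
```

`run_pipeline()` / `run_demo()` expose the same orchestration
programmatically, configured by a YAML file
(`inst/extdata/demo_config.yaml`).

## Layout

- `R/` — package code: data model and IO, spatial weights, synthetic
  generators, Moran/Gi*, GeoDetector, GTNNWR, pipeline.
- `analysis/` — numbered narrative drivers over the package.
- `tests/testthat/` — unit, property and acceptance tests (independent
  brute-force oracles live in `helper-oracles.R`).
- `vignettes/spatial-temporal-heterogeneity.Rmd` — the methods vignette:
  models, assumptions, parameter choices, limitations.
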