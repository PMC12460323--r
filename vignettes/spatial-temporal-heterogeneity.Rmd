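---
title: "Methods: spatial-temporal heterogeneity analysis of areal incidence panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spatial-temporal heterogeneity analysis of areal incidence panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the models implemented in `spatioepi`, the
assumptions behind them, the tunable parameters that matter, and the
design choices made where the methodology left the design open. The
package targets long-format areal disease panels — administrative units
observed yearly, with an incidence outcome (per 10,000 population) and
continuous covariates — and provides four analysis stages plus a
synthetic-data module that generates panels with known ground truth for
every stage.

## Data model

A `panel_dataset` is a validated long table of (unit, year) records with
an outcome, named covariates, and optional planar coordinates. The
validation is strict: unique (unit, year) pairs, a shared covariate set,
no missing outcomes or covariates (records with missing outcome are
dropped at read time with a message; missing covariates are rejected
rather than imputed, since the intended inputs are complete modelled
panels), and a contiguous year range per unit. Years are calendar
integers; the temporal coordinate used for distances is the offset from
the panel's first year, since only differences enter any computation.
Coordinates are planar — synthetic lattices use grid indices, and users
of real geographies are expected to supply projected centroids;
great-circle geometry is out of scope.

Windowed analyses use `bin_years()`: the span is cut into equal-width
bins (five years by default; a 30-year panel gives six windows) and each
unit's outcome is averaged within the bin. The width must divide the
span exactly — the windowed design is balanced by construction, which
makes the mean of the window means equal the period mean. For cumulative
full-period surfaces both the sum and the mean of yearly values are
exposed (`cumulative_surface()`); the sum is the default because summing
per-10,000 yearly rates is the natural cumulative scale, but nothing
downstream depends on the choice.

Spatial structure enters as a `spatial_weights` object: binary symmetric
contiguity read from a GAL neighbor list or derived from GeoJSON
polygons (queen contiguity links polygons sharing at least one boundary
vertex, rook requires a shared edge; queen is therefore always a
superset of rook). Asymmetric neighbor lists are rejected; islands are
retained with a warning and keep zero rows under row standardization.

## Global spatial autocorrelation

`global_morans_i()` computes

$$I = \frac{N}{S_0}\,
\frac{\sum_i \sum_j w_{ij}(x_i - \bar x)(x_j - \bar x)}
     {\sum_i (x_i-\bar x)^2}, \qquad S_0 = \sum_i\sum_j w_{ij},$$

with expectation $E[I] = -1/(N-1)$ under the null of no spatial
structure. Two analytic variances are available; the default is the
randomization (permutation-moment) variance, the standard choice in
areal epidemiology, with the normality-assumption variance behind a
flag — the source methodology states only the decision rule (Z-score
above 2.58 marks significant clustering at the 99% level), not the
variance assumption, so neither is asserted as canonical. Weights are
row-standardized by default, which is common practice and makes the
checkerboard identity exact: a perfect ±1 checkerboard on a
row-standardized rook lattice returns $I = -1$ exactly, because each
unit's neighbor average equals the negation of its own value. The raw
binary form follows from the same formula via $S_0$ and is available
with `standardize = FALSE`.

`morans_permutation()` supplements the analytic z with a random
relabelling test; the clustering-tail pseudo p-value is
$(1 + \#\{I_{perm} \ge I_{obs}\})/(1 + n_{perm})$. The test suite
verifies that the two inferences agree on strongly clustered fields and
that the pseudo p is calibrated (rejection near nominal) under the
null.

## Local hot spots

`getis_ord_gistar()` implements the self-inclusive local statistic: for
each unit the neighborhood sum (itself plus contiguity neighbors, all
weight 1) is standardized against the global mean and scale,

$$z_i = \frac{\sum_j w_{ij}x_j - \bar x \sum_j w_{ij}}
{S\sqrt{\left[N\sum_j w_{ij}^2 - (\sum_j w_{ij})^2\right]/(N-1)}},
\qquad S = \sqrt{\tfrac{1}{N}\sum_j x_j^2 - \bar x^2}.$$

Units are binned at the two-sided thresholds 1.645/1.960/2.576 into
90/95/99% hot (positive z) and cold (negative z) classes. Binary
weights with self-inclusion are the default, matching the classical
definition; a row-standardized variant is available. No multiple-testing
correction is applied by default — the bins reproduce the raw
confidence-class semantics used in applied hot-spot mapping — and the
z-scores are invariant under positive affine transforms of the field and
antisymmetric under negation, both asserted by tests.
`hotspot_persistence()` tabulates bins across time windows to summarize
how stable the hot and cold regions are.

## Stratified heterogeneity (factor and interaction detection)

The factor detector measures how much of the outcome variance a
categorical stratification of a covariate explains:

$$q = 1 - \frac{\sum_{h=1}^{L} N_h \sigma_h^2}{N \sigma^2}
    = 1 - \frac{SSW}{SST} \in [0, 1],$$

with population variances in both numerator and denominator (the ratio
is invariant to a consistent sample/population choice, which a test
asserts). Significance uses the framework's noncentral-F form:
$F = \frac{N-L}{L-1}\frac{q}{1-q}$ compared against
$F(L-1,\,N-L;\,\lambda)$ with
$\lambda = \big[\sum_h \bar y_h^2 - \frac{1}{N}(\sum_h \sqrt{N_h}\,\bar
y_h)^2\big]/\sigma^2$. Under random stratifications the test rejects at
or below nominal rates (verified over 1000 null simulations).

Continuous covariates are discretized by four schemes — equal interval,
geometric interval (edges in geometric progression; non-positive ranges
are shifted positive by $1 - \min x$ and mapped back), Jenks natural
breaks (exact dynamic-programming minimization of within-class sum of
squares, not a heuristic), and quantile. `optimal_discretization()`
evaluates every (scheme, class count) pair over a class range
(3–8 by default, a conventional span for ~50 areal units; the search
range is configurable within 2–12) and keeps the argmax of q. Ties
resolve deterministically: higher q, then fewer classes, then the scheme
order equal interval, geometric, natural breaks, quantile.

Interactions are detected on the overlay (cartesian cross-
classification) of two stratifications. Because the full overlay refines
both factors, $q_{12} \ge \max(q_1, q_2)$ up to floating point — the
weaken categories can only arise through empty-cell dropping or
tolerance effects, and the suite asserts the inequality on random pairs.
Classification follows the standard comparison rules with one numerical
concession: exact equality $q_{12} = q_1 + q_2$ ("independent") never
holds in floating point, so independence is declared when
$|q_{12} - (q_1+q_2)| \le 0.01$ and checked before the inequality rules.
Boundary cases (e.g. a factor interacted with itself, where
$q_{12} = q_1 = q_2$) fall through the strict inequalities to the
unilateral-weakening class.

The perturbation sensitivity analysis multiplies each covariate
elementwise by independent $\mathrm{Uniform}(1-f,\,1+f)$ noise
($f = 0.10$ by default), re-runs the factor detector, and averages
$|q' - q|/q$ over replicates (20 by default) and factors; the mean is
judged against the conventional 10% stability threshold. Two details
were genuinely open and are configurable: the noise is multiplicative
(a "10% perturbation" of a positive covariate most naturally scales it)
and the discretization edges are re-fitted on the perturbed values with
the baseline's scheme and class count, so that classification
sensitivity propagates; `freeze_edges = TRUE` holds the baseline edges
fixed instead. Factors with a zero baseline q are skipped with a
warning, since the relative change is undefined.

Factor screening operates per five-year window on window means (and on
full-period means for the pooled view), matching the granularity at
which windowed factor analyses are usually reported; whether pooled
records or window means are the right unit is a genuine choice, and the
window-mean route was chosen so that the factor tables share their
spatial support with the windowed clustering stages.

## Spatiotemporal weighted regression (GTNNWR)

The regression models spatiotemporal non-stationarity by modulating a
global linear fit with learned, observation-specific weights. For each
estimation point $p_i$ (a unit-year), spatial and temporal distances to
every training sample are computed (planar Euclidean; absolute year
difference), min-max scaled with bounds learned on the training set
only (validation/test distances may exceed 1 — no leakage). A small
proximity network (input 2, hidden widths `[3]`, linear output) fuses
each $(d^s_{ij}, d^t_{ij})$ pair into one proximity $d^{st}_{ij}$; the
weight network maps the point's proximity profile (length = number of
training samples) through hidden layers (`[512, 256, 64]` by default)
to one multiplicative weight per coefficient,
$w_i \in \mathbb{R}^{p+1}$. Predictions are

$$\hat y_i = \sum_{k=0}^{p} w_{ik}\,\beta_k^{OLS}\,x_{ik},$$

so the coefficient surfaces $\beta_{ik} = w_{ik}\beta_k^{OLS}$ vary over
space and time while remaining anchored to an interpretable global fit.
Forcing $w \equiv 1$ reproduces the global least-squares predictions to
machine precision — a reduction identity the tests assert. The
per-coefficient weight output (rather than a single shared weight)
follows the reading that each explanatory variable's influence is
modulated individually.

Training minimizes the normalized mean squared error
$\sum_i(\hat y_i - y_i)^2 / (n\,c^2)$ on the training split with
Adadelta (decay 0.95, $\epsilon = 10^{-6}$, base rate 1) and a
multistep schedule multiplying the rate by 0.8 at epochs
1000/2000/3000/4000; hidden layers of the weight network use a leaky
rectifier with batch normalization and dropout 0.4; the proximity
network is a plain leaky-rectifier stack. The normalizer $c$ is the
training-outcome range by default and is configurable (squared-mean
normalization is also offered) — published NRMSE/NMAE figures do not
always state their normalizer, so it is exposed rather than asserted.
Validation NMSE is checked every 25 epochs and the best-validation
parameter snapshot (including batch-norm running statistics) is
retained; early stopping by patience is available but off by default.
Training is full-batch — at the intended scale (a few thousand records)
this is faster and exactly reproducible; all randomness (split,
initialization, dropout) flows from explicit seeds, so fixed seeds give
bit-identical histories on one platform. Hold-out validation
(75/10/15 at seed 48, sizes rounded with the remainder to training) is
used rather than k-fold, keeping one fixed reference set for the
proximity profiles.

One engineering note: the networks are implemented directly in base-R
matrix algebra (hand-derived backward passes, including the batch-norm
backward). Since proximities depend only on the unit pair and the year
lag, the proximity network runs over the unique distance pairs (a ~20x
compression on a lattice panel) and results are scattered back — this
is exact, not an approximation.

## Synthetic data and what passing tests mean

Three generators provide ground truth:

- `simulate_sar_field()` draws $y = (I - \rho W)^{-1}\varepsilon$ on a
  lattice, giving fields whose clustering strength is controlled by
  $\rho$ ($\rho = 0$ is iid, expected $I = -1/(N-1)$).
- `simulate_stratified_covariate()` constructs a field whose
  stratification explains exactly a requested share of variance: stratum
  means are separated, residuals centered within strata, and the
  residual scale solved in closed form so the realized $1 - SSW/SST$
  equals the request to $10^{-10}$ — a closed loop with the factor
  detector.
- `simulate_nonstationary_panel()` builds a 6 × 8 lattice × 30-year
  panel (48 units, mirroring a 48-state contiguous study area) with iid
  standard-Normal covariates and coefficient surfaces supplied as
  functions of grid position and year offset. The default surfaces are:
  intercept $2 + 0.5\,y/n_{rows} - 0.3\,t/n_{years}$; first covariate
  $1 + 0.5\,x/n_{cols} + 0.3\,t/n_{years}$ (the nonstationary signal);
  second covariate constant 0.5; third covariate 0 (a planted null used
  to check that irrelevant factors rank last). Observation noise is
  Normal with sd 0.5.

The standard recovery benchmark (`gtnnwr_benchmark()`) fixes this
generator at seed 2024, splits at seed 48, and trains 3000 epochs; the
epoch count exercises the full milestone schedule while keeping the
experiment at desk scale, and a flag restores the 15,000-epoch default.
The benchmark's weight-network widths are (128, 64) rather than the
(512, 256, 64) package default: at 1080 training records the narrower
network reaches the same validation plateau in a fraction of the time,
and benchmark sizing should not dominate its runtime. With these
conditions the model must beat the global-OLS test RMSE, reach
validation R² ≥ 0.85, and recover the first coefficient surface with
Pearson r ≥ 0.7. One caveat worth stating: with noise sd 0.5 the
validation noise-floor R² is about 0.86, so the R² bar sits close to
the theoretical ceiling — the fit achieves ~0.856, i.e. essentially all
explainable variance.

What the synthetic panels do **not** emulate: realistic covariate
marginals or cross-correlations (covariates are iid Normal by design, to
isolate coefficient recovery), demographic age-standardization, irregular
state geometries, or measurement error in covariates. Passing the suite
shows the statistics and the estimator are implemented correctly and
that the estimator recovers known structure under controlled conditions;
it does not validate substantive epidemiological conclusions on real
panels.

## Numerical choices and degenerate inputs

- Zero-variance fields, constant covariates, single strata, and empty
  overlays are hard errors (or a warning + convention, e.g. q = 0 for a
  single stratum), never silent results.
- Quantile bins with duplicated edges collapse (unique edges) and the
  class count adjusts; bins left empty are dropped and strata relabelled.
- On frozen discretization edges, perturbed values outside the edge
  range clamp to the outer bins.
- Large noncentrality saturates the noncentral-F tail; the underlying
  routine's precision warning is suppressed there because the p-value is
  indistinguishable from 0 at the scales involved.
- Moran permutation draws, SAR innovations, splits, network
  initialization and dropout all take explicit seeds and restore the
  caller's RNG state.

## Problem sizes

The shipped analysis scripts and the test suite run at the study's own
scale: 48 units × 30 years (1440 records) for the benchmark and the
demo pipeline; the multi-seed regression-vs-OLS comparison uses a
reduced 5 × 5 × 12 configuration with 500-epoch fits across 20 seeds,
which preserves the comparison's meaning while keeping the property
cheap to evaluate repeatedly.

## Known limitations

- Gi* p-values are pointwise; the 90/95/99 bins are descriptive classes,
  not familywise-corrected inferences (an FDR option exists).
- The GeoDetector significance test conditions on the *selected*
  discretization; selection-induced optimism in q is inherent to the
  optimal-discretization design and is why the null-calibration test
  uses fixed random strata.
- The weighted regression's proximity profile is tied to the training
  reference set; records far outside the training support (in space or
  time) receive extrapolated weights.
- Training is CPU-bound dense linear algebra; panels beyond ~10k records
  would need mini-batching (available) and ideally a compiled backend.
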