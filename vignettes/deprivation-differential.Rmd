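---
title: "Deprivation differentials and small-area morbidity: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deprivation differentials and small-area morbidity: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(depdiff)
```

## The model

The unit of analysis is a small area (on the order of 1,500 residents)
with a composite deprivation score (IMD-like, higher = more deprived)
and, per morbidity outcome, a numerator count and a denominator adult
population. The two outcomes carried through the package are the share
of adults reporting 'not good' general health and the share reporting a
limiting long-term illness (LLTI).

Write $d_i$ for the deprivation score of area $i$ and
$\mathrm{ALD}_i = \sum_j w_{ij} d_j$ for the weighted mean over its
queen-contiguity neighbours (the *adjacent locality deprivation*). The
pair $(d_i, \mathrm{ALD}_i)$ is strongly collinear whenever deprivation
is spatially autocorrelated, which is exactly the situation of interest.
The package rotates the mean-centred pair by the eigenvectors of its
$2\times 2$ covariance matrix:

$$\mathrm{PC1}_i = a\,(d_i - \bar d) + b\,(\mathrm{ALD}_i -
\overline{\mathrm{ALD}}), \qquad
\mathrm{PC2}_i = b\,(d_i - \bar d) - a\,(\mathrm{ALD}_i -
\overline{\mathrm{ALD}}),$$

with $a, b > 0$ and $a^2 + b^2 = 1$. PC1 (*target area deprivation*)
tracks the shared level of deprivation of the area and its
surroundings; PC2 (*deprivation differential*) is positive when the
area is more deprived than its neighbours. The sample correlation of
the two score vectors is zero by construction, and
$\mathrm{var}(\mathrm{PC1}) + \mathrm{var}(\mathrm{PC2}) =
\mathrm{var}(d) + \mathrm{var}(\mathrm{ALD})$ exactly.

Each outcome is converted to a percentage $100\,y_i/n_i$, log10
transformed (percentages, not proportions, are the canonical pre-log
scale; standardized regression is invariant to the choice), and
regressed on the z-scored components. With orthogonal predictors the
multivariate standardized slopes $\beta_1, \beta_2$ equal the bivariate
ones and the unadjusted $R^2$ of the joint model is the sum of the two
bivariate $R^2$s — both identities are asserted in the test suite and
reported as run diagnostics. The segmented analysis re-estimates the
two-predictor model inside each population segment, re-z-scoring the
outcome and both predictors *within* the segment, and summarizes each
segment by $\beta_1/\beta_2$. A positive $\beta_2$ matches the
psychosocial account of relative deprivation; a negative $\beta_2$
would match the neo-material account — the design distinguishes the
two by the sign.

## Design choices where the method was genuinely open

**Covariance versus correlation PCA.** The rotation uses the covariance
matrix of the unstandardized pair. Correlation-matrix PCA of two
variables always yields loadings $\pm 1/\sqrt2 \approx (0.71, 0.71)$;
the asymmetric loadings (near 0.76/0.64) that this family of analyses
reports can only arise from the covariance matrix, which is therefore
the default. A `mode = "correlation"` option exists for sensitivity
analysis.

**Score scaling.** Component scores are raw projections of the centred
data, not rescaled to unit variance. Reported score ranges are then
data-dependent, and the standardized regression downstream is
indifferent to the choice.

**Sign convention and ties.** Eigenvectors are sign-fixed so that both
PC1 loadings are positive and PC2 loads positively on the area's own
score and negatively on the neighbour mean; this makes "more deprived
than the neighbours" a positive differential. Exactly tied eigenvalues
(a measure-zero case) assign PC1 to the eigenvector with the larger
loading on the area's own score.

**Neighbour weights.** "Weighted mean of neighbours" is implemented as
row-standardized binary queen weights — the standard default in spatial
analysis — with a custom per-edge weight hook (weights must be
nonnegative and sum to one per area) for population- or
boundary-length-weighted variants. The decomposition is agnostic to
the choice.

**Islands.** Areas with no neighbours have no defined ALD. They are
excluded from every model stage with a warning and reconciled in the
run report (`areas in = retained + islands`); imputing a value would
contaminate the differential.

**Zero numerators.** `compute_outcomes()` errors by default on a zero
count, naming the areas, because log10 is undefined there; an opt-in
continuity correction adds 0.5 to zero numerators. `run_simulation()`
opts into the correction, because under a large residual SD the
generator legitimately produces areas whose expected count is below
one (see below).

**Tertiles.** The tertile split is rank-based with remainder areas
allocated to the most-deprived groups first and ties in the score
broken by area identifier, so group sizes differ by at most one and the
assignment is fully deterministic.

**Segment ordering.** Segment report rows are sorted by descending
$\beta_1/\beta_2$, ties broken by segment name; a ratio whose
denominator is numerically zero ($|\beta_2| \le 10^{-9}$) is reported
as `NA` and sorts last. Ratios are displayed to 3 decimals; CSVs carry
full precision. Segments below 30 areas are dropped with a warning
rather than an error.

**No age standardization and no spatial-error inference.** The
morbidity shares are used as reported, and the OLS p-values make no
correction for residual spatial autocorrelation; both choices mirror
the study design this pipeline operationalizes and are stated
limitations, not oversights.

## The synthetic-data generator

`simulate_region()` emulates the statistical structure the analysis
assumes, so every downstream stage is testable without external data:

* **Deprivation field.** Iid standard-normal innovations on a
  `grid_rows x grid_cols` queen lattice, followed by `smoothing_rounds`
  passes of $d \leftarrow (1-\rho)\,d + \rho\,(\text{neighbour mean of }
  d)$, then an affine shift to a nonnegative, IMD-like scale. The
  mixing weight $\rho$ (`autocorr_mix`) controls spatial
  autocorrelation and hence the IMD/ALD collinearity the method exists
  to resolve. This moving-average smoother was chosen over a CAR/SAR
  model as the simplest mechanism producing the required collinearity;
  swapping in a CAR draw would touch one function.
* **Outcomes.** The latent log10 percentage is $y_i = \mu + b_1
  z(\mathrm{PC1}_i) + b_2 z(\mathrm{PC2}_i) + \sigma \varepsilon_i$,
  where the components are computed from the simulated field *by the
  real pipeline*, so the generative effects act on exactly the
  predictors the analysis uses. The implied proportion $10^{y_i}/100$
  is clipped to $[1/(n_i+2),\, 1 - 1/(n_i+2)]$ (keeping it a valid
  binomial probability) and counts are drawn
  $\mathrm{Binomial}(n_i, p_i)$. The 'not good health' baseline is
  $\mu$ = `baseline_log10_pct` (default 0.95, about 9%); LLTI uses
  $\mu + 0.31$ (about 18%), reflecting the typical gap between the two
  census indicators, with an independent noise draw.
* **Denominators.** Uniform integers on `denominator_range` (default
  900–2100, centred near the typical ~1500 adult population of such
  areas) — a deliberate simplification, not a claim about the true
  population-size distribution.
* **Segments.** Quantile bins of the deprivation field (default 13,
  the size of a typical geodemographic "tree" classification), with a
  seeded 10% of areas reassigned to an adjacent bin so segments
  correlate with, but are not determined by, deprivation.

Default generator parameters (`b1 = 0.6`, `b2 = 0.3`, `sigma = 0.74`,
$\rho$ = 0.8, 5 rounds, 50x50 grid) define the canonical synthetic
study conditions used by the recovery checks. For orthonormal
standardized predictors the population standardized slopes are
$\beta_k = b_k / \sqrt{b_1^2 + b_2^2 + \sigma^2}$
(`expected_std_slopes()`), about 0.601 and 0.300 at the defaults —
deliberately placed near the magnitudes this kind of national analysis
reports.

What the generator does *not* emulate: real national deprivation
distributions (multi-domain, right-skewed), irregular area geography
and edge effects, spatially structured residuals beyond what the field
smoothing induces, migration, and age structure. Passing recovery tests
therefore demonstrate that the pipeline estimates what it claims under
its own assumptions — not that those assumptions hold for any given
real dataset.

## Numerical notes

* With $\sigma = 0.74$ on the log10-percentage scale the latent model
  places a tail of areas at expected counts below one; sampled zero
  counts are expected, which is why simulation runs use the continuity
  correction, and the clipping rule keeps the realized percentage
  strictly inside (0, 100). The attenuation induced by clipping plus
  the correction is small: recovery errors on the default lattice are
  typically 0.005–0.03, inside the ±0.05 acceptance band.
* Degenerate inputs fail loudly: constant deprivation vectors, constant
  or collinear predictors (design condition number above $10^8$),
  mismatched area sets, numerators exceeding denominators, and
  over-dispersed generator configurations (non-finite latent values)
  all raise errors naming the offending field or areas.
* Determinism: a `simulation_config` seed makes the whole region —
  field, denominators, counts, segments — bit-identical across calls,
  and `run_analysis()` output files are byte-identical given identical
  inputs. All joins are by area identifier, never row order.

## Problem sizes used by the checks

The test suite exercises decomposition and OLS oracles on hundreds of
random small instances (8–120 areas), polygon/lattice equivalence up to
7x7 grids, and full-pipeline recovery on 20x20 to 50x50 lattices; the
null-scenario tertile check uses the 50x50 lattice so that each tertile
holds ~833 areas, putting the 0.1 slope bound at roughly three standard
errors of a null correlation. The acceptance script's simulation runs
on the canonical 50x50 conditions. These sizes keep the whole suite in
well under a minute per file while leaving the statistical assertions
comfortably powered.

## Known limitations

Inference is ordinary least squares: p-values ignore residual spatial
autocorrelation, so significance on strongly autocorrelated residual
fields is optimistic. The segmentation consumes labels (or tertiles);
it does not implement a geodemographic classifier. Only two deprivation
measures enter the decomposition; extending beyond the 2x2 case is out
of scope. Edge lists are trusted as given; only the polygon path
validates geometry, and only GeoJSON polygon input is supported.
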