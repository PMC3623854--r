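# depdiff

Small-area ecological analysis of how an area's deprivation and its
**deprivation differential** — how much more (or less) deprived it is than
its contiguous neighbours — jointly predict self-reported morbidity.

## The problem and the method

Area-level studies of deprivation and health face a collinearity problem:
a small area's deprivation index (e.g. an IMD score) is strongly
correlated with the mean index of the areas surrounding it, so the
separate contributions of "being deprived" and "being more deprived than
your neighbours" cannot be read off a naive regression. The pipeline
implemented here resolves this in four steps:

1. **Queen contiguity.** Two areas are neighbours if their boundaries
   share at least one point (an edge or a single vertex). Graphs can be
   built from a regular lattice, from GeoJSON polygons, or from a
   precomputed edge list.
2. **Spatial lag.** For each area, the adjacent locality deprivation
   (ALD) is the weighted mean of its neighbours' deprivation scores
   (row-standardized binary weights by default, i.e. the simple
   neighbour mean). Areas without neighbours are excluded, never imputed.
3. **Orthogonalization.** The pair (IMD, ALD) is rotated by principal
   components of its 2x2 covariance matrix into two *exactly
   uncorrelated* predictors: PC1 = a·IMD + b·ALD (a, b > 0), the
   **target area deprivation**, and PC2 = b·IMD − a·ALD, the
   **deprivation differential**, which is positive for areas more
   deprived than their surroundings.
4. **Standardized regression.** Morbidity outcomes (the percentage of
   adults aged 15–65 reporting 'not good' general health, and the
   percentage reporting a limiting long-term illness, LLTI) are
   log10-transformed and regressed on z-scored PC1 and PC2, bivariately
   and jointly. Because the predictors are orthogonal, the multivariate
   standardized slopes β₁, β₂ equal the bivariate ones and the
   unadjusted R² is exactly additive. The models are then re-estimated
   within deprivation tertiles or geodemographic segments
   (re-standardizing within each segment) and summarized by the ratio
   β₁/β₂ — how many times stronger the effect of an area's own
   deprivation is than the effect of its differential. A positive β₂ is
   the psychosocial signature (relative deprivation harms health); a
   negative β₂ would support a neo-material reading.

Because the real national inputs (deprivation index and census morbidity
tables) are external downloads, the package ships a first-class
synthetic-data generator: spatially autocorrelated deprivation on a
queen-contiguity lattice (iterative neighbour-mean mixing), a latent
linear model for log10 morbidity percentages on the two orthogonal
components, binomial count sampling given area denominators, and segment
labels correlated with deprivation rank. The generator's closed-form
implied slopes, `b_k / sqrt(b1² + b2² + σ²)`, are used to verify that
the full pipeline recovers known effects.

## Worked example

```r
library(depdiff)
cfg <- simulation_config(grid_rows = 20, grid_cols = 20,
                         noise_sd = 0.3, seed = 11)
sim <- run_simulation(cfg)
print(sim$report)
```

```
Deprivation-differential analysis run
  areas: 400 in, 400 retained, 0 island(s)
  PC1 = 0.76 IMD + 0.65 ALD; PC2 = 0.65 IMD - 0.76 ALD
  PC score correlation: -9.16e-16
llti (n = 400)
  beta1 (target area deprivation)    0.819 ***
  beta2 (deprivation differential)   0.397 ***
  adjusted R2: bivariate 0.670 + 0.155 ; multivariate 0.827
not_good_health (n = 400)
  beta1 (target area deprivation)    0.801 ***
  beta2 (deprivation differential)   0.410 ***
  adjusted R2: bivariate 0.640 + 0.166 ; multivariate 0.808
Segmented regression (imd_tertiles), outcome: llti
                        segment deprivation_rank beta1 stars1 beta2 stars2
   Lower third (least deprived)                3 0.600    *** 0.592    ***
 Medium third (middle deprived)                2 0.405    *** 0.700    ***
    Upper third (most deprived)                1 0.292    *** 0.605    ***
 ratio n_areas
 1.014     133
 0.579     133
 0.482     134
...
```

Reading the output: the deprivation field was generated on a 20x20
lattice with neighbour-mixing weight 0.8, so IMD and ALD are highly
collinear and the PCA loadings land near (0.76, 0.65). The score
correlation of the two components is zero to machine precision — the
property the orthogonalization exists to deliver. Both the area's own
deprivation (β₁) and its differential (β₂) carry significant positive
standardized effects on log10 morbidity, and the multivariate adjusted
R² decomposes into the two bivariate contributions. The tertile table
re-estimates the model within thirds of the deprivation distribution;
the ratio column shows the differential mattering relatively more in
the least deprived third (ratio near 1) than in the most deprived.

`sim$recovery` compares the fitted standardized slopes with the
generator's closed-form targets:

```
         outcome                predictor    fitted  expected  abs_error
            llti       target_deprivation 0.8189014 0.8164966 0.00240482
            llti deprivation_differential 0.3966158 0.4082483 0.01163249
 not_good_health       target_deprivation 0.8005182 0.8164966 0.01597841
 not_good_health deprivation_differential 0.4097941 0.4082483 0.00154577
```

A thin command-line wrapper with `simulate` and `analyze` subcommands is
installed at `inst/cli/depdiff.R`; `analyze` accepts an area-table CSV
(`area_id, imd, notgood_count, llti_count, denominator[, segment]`) plus
either an edge-list CSV or a GeoJSON polygon file.

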