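# betadecay

Distance decay of community similarity, Mantel tests and variation
partitioning for presence–absence data.

## What problem this solves

Community ecologists studying beta diversity ask how fast species
composition turns over across a landscape and which processes — dispersal
limitation, niche filtering, or geographic isolation — drive that turnover.
The standard workflow starts from a site × species incidence matrix,
computes pairwise similarity, regresses similarity on geographic distance,
and then confronts the similarity matrix with explanatory distance matrices.
betadecay packages that workflow end to end for incidence data at the scale
of counties, grid cells or plots, with a synthetic mountain-landscape
generator so every stage can be tested against data with known ground
truth.

The core statistics:

* **Similarity**: Jaccard `J = a/(a+b+c)` and Simpson `a/(a+min(b,c))`
  (richness-insensitive), where `a` is the shared species count and `b`, `c`
  the counts unique to each site.
* **Distance decay**: similarity `y` vs geographic distance `x` fit by OLS
  in three forms — linear `y = ax + b`, logarithmic `y = a ln x + b`,
  exponential `y = b e^(ax)` — each with a matrix-permutation test that
  respects the non-independence of site pairs.
* **Halving distance**: the distance at which the fitted curve predicts half
  the initial similarity `S0` (default: the maximum observed pairwise
  similarity), solved in closed form. Smaller halving distance = faster
  turnover; it is comparable across regions, directions and elevation
  zones.
* **Explanatory matrices**: geodesic WGS84 distance between centroids (km),
  Euclidean environmental distance on retained correlation-matrix PCA axes,
  and absolute differences in mean elevation (isolation proxy), elevation
  range (heterogeneity proxy) and area.
* **Attribution**: simple and partial Mantel tests, multiple regression on
  distance matrices (MRM), and seven-fraction variation partitioning of the
  full-model R² into pure and joint effects of geographic distance (G),
  environmental distance (E) and mean-elevation difference (A) by
  inclusion–exclusion.

## Worked example

```r
library(betadecay)

d <- synth_survey(seed = 1)      # 164 sites x 191 species, survey-shaped
d$occurrence
#> occurrence_matrix: 164 sites x 191 species (13366 site pairs), richness 17-54

sim <- similarity_matrix(d$occurrence, "jaccard")
geo <- geo_distance_matrix(d$sites)
fit <- permutation_significance(sim, geo, "exponential", n_perm = 199, seed = 1)
fit
#> decay_fit [exponential]: a = -0.00096123, b = 0.827, r2 = 0.781, n = 13366
#>   S0 = 1, halving distance = 523 km, permutation p = 0.005
```

Similarity declines roughly 0.1 % per km (`a`), the regression explains 78 %
of pair-level variance on the log scale, and compositional similarity halves
over about 523 km; the permutation p (199 site-label permutations of the
similarity matrix, rows and columns moved together) is the minimum
attainable, so the decay is far stronger than random site relabeling
produces.

```r
pca <- env_pca(d$sites)                       # correlation-matrix PCA, 95% target
vp <- partition3(sim, geo,
                 env_distance_matrix(pca),
                 scalar_diff_matrix(d$sites, "mean_elev"))
vp
#> Variation partitioning (fractions of similarity variance):
#>   pure_G      21.2%
#>   pure_E       0.0%
#>   pure_A       0.0%
#>   joint_GE    55.9%
#>   joint_GA     9.7%
#>   joint_EA    -0.0%
#>   joint_GEA   -9.6%
#>   residual    22.8%
#>   total explained: 77.2%
```

Geographic distance alone carries 21 % of the variance; most of the rest is
shared between geography and the spatially structured environment
(`joint_GE`), exactly what the generator built in (dispersal limitation plus
an environment that tracks location). Joint fractions are differences of
R² values and may legitimately be negative; they are reported as computed.

Zonal comparisons (`zone_spec()` + `zone_decay_report()`) produce per-band
decay tables, and `run_pipeline()` orchestrates the whole analysis from two
CSV files to a results directory; see the vignette in `vignettes/` for the
models, conventions and validation experiments, and
`inst/scripts/run_pipeline.R` for a shell entry point.

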