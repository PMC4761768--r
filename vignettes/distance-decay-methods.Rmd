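---
title: "Distance decay of community similarity: models, tests and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Distance decay of community similarity: models, tests and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(betadecay)
```

## The scientific problem

Species turnover (beta diversity) between survey units — here, county-scale
assemblages in a mountainous region — usually increases with the geographic
distance separating them. Three families of processes can produce that
pattern: **dispersal limitation** (organisms simply fail to reach distant
sites), **niche filtering** (distant sites have different environments, and
species track environments), and **geographic isolation** (barriers such as
mountain ridges, and the increasing isolation of high-elevation sites, cut
otherwise reachable sites apart). betadecay implements the statistical
toolkit used to describe the decay pattern and to apportion it among those
processes, together with a synthetic landscape generator in which each
process can be switched on independently, so that every statistic can be
validated against data with known ground truth.

## Similarity indices

For a pair of sites with `a` shared species, and `b` and `c` species unique
to each side, the package computes

* **Jaccard similarity** `J = a / (a + b + c)` — the fraction of the pooled
  species list that is shared; and
* **Simpson similarity** `a / (a + min(b, c))` — which ignores richness
  differences, scoring a nested assemblage pair as 1, and therefore isolates
  true turnover from nestedness.

Simpson is never smaller than Jaccard; both are computed from binary
incidence only, and abundance input is rejected rather than silently
thresholded. Sites with empty assemblages are rejected at construction,
which guarantees both indices are defined for every pair.

## Decay models and the halving distance

Similarity `y` against geographic distance `x` (km) is fit in three
classical forms, each by ordinary least squares on its own linearising
scale:

| form | model | OLS scale |
|---|---|---|
| linear | `y = a x + b` | `y` on `x` |
| logarithmic | `y = a ln(x) + b` | `y` on `ln x` |
| exponential | `y = b e^(a x)` | `ln y` on `x` |

R² is reported on the transformed scale on which the regression was run, so
the three forms can be compared side by side the way regional decay tables
print them. Pairs a transform cannot use — zero distances for the
logarithmic form, zero similarities for the exponential — are excluded with
a logged count rather than fudged with pseudo-counts; the exclusion rule is
applied identically when refitting under permutation.

The headline statistic is the **halving distance**: the distance at which
the fitted curve predicts half the initial similarity `S0`. It is solved in
closed form (`(b − S0/2)/(−a)`, `exp((S0/2 − b)/a)`, and `ln(2b/S0)/(−a)`
respectively), returned at full precision, and rounded to whole kilometres
only for display. Because the inverse is exact, plugging the halving
distance back into the model reproduces `S0/2` to machine precision — a
round-trip the test suite asserts for random decaying fits of all three
forms.

`S0` defaults to the **maximum observed pairwise similarity** of the region
being fit, which equals 1 whenever the region contains at least one pair of
identical assemblages and naturally falls below 1 in small or heterogeneous
zones. The published tables this statistic descends from do not spell out
their `S0` convention; maximum-observed reproduces their value of 1 for
every region containing an identical pair, so it is the default, and a fixed
user-supplied `S0` is accepted wherever the default is not wanted.

## Permutation significance

The n(n−1)/2 site pairs entering these regressions are not independent —
each site takes part in n−1 pairs — so parametric regression p-values are
anticonservative. Significance instead comes from a matrix permutation
test: site labels of the similarity matrix are permuted, **rows and columns
together** (permuting rows alone would destroy the symmetry of the matrix
and the exchangeability the null requires; the suite tests this), the
regression is refit, and the one-sided add-one p-value is
`(1 + #[R²_perm ≥ R²_obs]) / (n_perm + 1)` with 1000 permutations by
default. When fewer than `n_perm` distinct permutations exist the test
switches to exhaustive enumeration over all n! relabelings (with the
identity included) and reports the exact proportion. The test suite checks
the empirical type-I error of this machinery on 500 null datasets and the
exact agreement of the exhaustive path with an independently enumerated
oracle.

## Explanatory distance matrices

* **Geographic distance**: geodesic distance between site centroids on the
  WGS84 ellipsoid (Karney's algorithm), in km. A haversine alternative is
  provided and agrees within 0.5 %. Sites are treated as points (centroids);
  polygon-aware distances are out of scope.
* **Environmental distance**: the environmental variables are standardised
  and subjected to PCA on their correlation matrix; axes are retained up to
  a cumulative explained-variance target (default 0.95) or a fixed count;
  the distance is the **unweighted** Euclidean distance in the retained
  score space. Weighting axes by eigenvalue is a defensible alternative, but
  the unweighted form follows the standard description of this method
  ("Euclidean distance in the space of the retained components") literally;
  the choice matters only when trailing retained axes are interpreted
  differently from leading ones.
* **Isolation and heterogeneity proxies**: absolute pairwise differences in
  mean elevation (isolation) and in within-site elevation range
  (environmental heterogeneity), plus area difference as a nuisance check.

All pairwise matrices share one canonical unrolling — pairs (i, j) with
i < j, enumerated row by row of the lower triangle — enforced by a single
`pair_vector()` used by every downstream statistic, so matrices can never be
misaligned by ordering conventions.

## Mantel tests, MRM and variation partitioning

`mantel_simple()` correlates two pair vectors and permutes one matrix's site
labels; p-values are two-sided by default because decay correlations are
signed. `mantel_partial()` removes the conditioning matrices from both sides
by OLS on the pair vectors and permutes the **residuals of the first matrix,
folded back into symmetric-matrix form**, so the permutation stays
row/column-coherent. Raw-matrix permutation is the main alternative; the
residual scheme is the one used by the distance-matrix regression lineage
this package follows, and it extends naturally to multiple conditioning
matrices via multivariate OLS residuals.

`mrm()` regresses the similarity pair vector on several predictor pair
vectors at once, with significance again from whole-matrix permutation of
the response. `partition3()` runs the seven subset regressions on
geographic distance (G), environmental distance (E) and mean-elevation
difference (A) and solves the Venn diagram by inclusion–exclusion: pure
fractions are differences against the complementary two-predictor model,
and joint fractions absorb the rest. Negative joint fractions are
legitimate (suppression) and are **reported as computed, never clipped**;
the fractions always sum to the full-model R² to 1e−10, which the suite
asserts on random inputs. Plain R² (not adjusted) is used throughout,
matching the way the partitioning is defined from coefficients of
determination. `incremental_r2()` reports the ΔR² of an extra matrix over a
base set and tolerates an extra matrix aliased with the base (ΔR² = 0).

## Zonation

`zone_spec()` cuts sites into bands along latitude, longitude or mean
elevation. Intervals are half-open `[low, high)` with the top interval
closed — a convention the published "<2000 m", "2000–3000 m", ">4000 m"
style leaves ambiguous; one convention applied everywhere is what matters,
and a site exactly on an internal edge goes to the upper band.
`zone_decay_report()` rebuilds similarity and distance matrices **within**
each zone (species unrecorded in a zone are dropped; `S0` is recomputed
zone-locally, which is why small zones show initial similarities below 1)
and refits the decay forms per zone. Zones with fewer than 3 sites are
skipped with a warning, mirroring the way data-deficient bands are excluded
from regional analyses by configuration, not inference.

## The synthetic landscape generator

`generate_landscape()` places sites on a jittered grid, raises a parametric
ridge field (count, orientation, amplitude) above a valley floor, derives
each site's mean elevation and local relief from that surface, and blends
four smooth environmental fields with independent noise under one spatial
structuring knob (`env_spatial_corr`). `generate_occurrence()` gives each
species a range centre, an exponential range radius around
`range_scale_km`, and a niche optimum on the first environmental axis;
presence requires both effective distance below the radius and
environmental mismatch below `niche_breadth`. Isolation enters through the
effective distance: each ridge crossed multiplies distance by
`1 + barrier_penalty`, and distances from a site are further inflated by
`1 + barrier_elev_scaling × elev/max(elev)`, so high sites are
systematically harder to reach.

Numerical choices worth knowing:

* **Richness calibration.** All radii are rescaled by a single multiplier
  found by bisection (≤ 40 steps) so that every site's richness lands in
  `target_richness`. The multiplier stays exactly 1 when the band already
  holds and otherwise moves as little as possible — a minimal-intervention
  rule that keeps the configured `range_scale_km` meaningful (an earlier,
  looser rule could silently cancel it). Species stranded with no site are
  re-seeded onto an occupied location.
* **Determinism.** All randomness flows from one seed through an RNG whose
  state is saved and restored, so identical configurations give identical
  tables and library calls never disturb the caller's RNG.
* **Default shape.** `synth_survey()` produces the default end-to-end
  fixture: 164 sites × 191 species over 92–106° E × 21–35° N with per-site
  richness confined to 17–87 — the shape of a county-level mountain survey —
  with dispersal limitation (400 km mean range), mild spatially structured
  niche filtering, and no barriers.

What the generator does **not** emulate: real surveys have uneven sampling
effort, spatially autocorrelated detection failures, taxonomic lumping, and
range shapes that follow valleys rather than circles. Tests passing on
synthetic data therefore validate the statistical machinery and the
direction of mechanism recovery, not the field realism of any particular
parameter value.

## Validation experiments built into the test suite

The suite's deeper experiments, and the problem sizes they use (chosen to
keep a full run around half a minute):

* **Type-I calibration**: 500 null datasets of 20 sites, 199 permutations
  each, for both the decay permutation test and the simple Mantel test;
  empirical rejection at α = 0.05 must land in [0.03, 0.07].
* **Algebraic oracles**: MRM and partial Mantel against explicit
  normal-equation solutions on 6-site instances (1e−10), and permutation
  p-values against full 120-permutation enumeration at 5 sites.
* **Mechanism recovery**: with only dispersal enabled (30 sites, 60
  species, environment pure noise), pure-G must be the largest pure
  fraction; with only niche filtering enabled, pure-E must be — each in at
  least 8 of 10 seeds.
* **Isolation gradient**: with `barrier_elev_scaling = 3` (80 sites, 120
  species), the logarithmic-form halving distance must decrease from the
  lowest to the highest of three elevation zones in at least 8 of 10 seeds.
  The logarithmic form is used here because its halving distance is defined
  for any decaying fit, whereas the linear form's can be undefined when
  turnover is fast enough that the fitted intercept falls below `S0/2` —
  which is precisely what strong isolation produces in the top zone.
* **Range-scale sweep**: mean fitted halving distance must be
  rank-monotone in `range_scale_km` over {100, 200, 400} km in a compact
  (6° × 6°) domain, where all three scales leave enough shared species for
  a stable fit.

## Known limitations

* The exponential form's R² is computed on the log scale on which it is
  fit; comparing it against the linear form's R² compares fits on
  different scales (the same caveat applies to any side-by-side decay
  table).
* Halving distances extrapolate the fitted curve; for the logarithmic form
  with small |a| the solution can exceed the observed distance range, and
  it should then be read as "no halving within the study extent".
* Partial Mantel tests with residual permutation have known inflated
  type-I error under strong spatial autocorrelation of both matrices; the
  package implements the standard method, not a fix for that literature.
* The barrier model counts straight-line ridge crossings; it creates
  anisotropic turnover cheaply but is not a least-cost-path model.
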