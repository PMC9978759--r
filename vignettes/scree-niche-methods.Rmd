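---
title: "Methods: terrain predictors, the balanced resampling test, and criterion B2"
author: "screeNiche"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: terrain predictors, the balanced resampling test, and criterion B2}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(screeNiche)
```

## The question this package answers

Some narrowly endemic mountain plants — classic examples are scree
specialists of Mediterranean limestone massifs — occur in a handful of
small patches even though apparently similar habitat is widespread. When
survey data consist of a few presences and a few dozen visited-but-empty
sites, and the study extent is far too small for climatic predictors to
vary meaningfully, the natural hypothesis is *micro*-topographic: the
species may be confined to concave microsites (small valleys at the foot
of scree fields) where avalanche snow accumulates and moisture persists.

screeNiche implements the full chain needed to test that hypothesis:
six 3×3-neighbourhood terrain predictors from a DEM, extraction at survey
points, a balanced resampling significance test designed for strongly
unbalanced presence/absence data, and an IUCN criterion-B2 threat
assessment. A seeded synthetic-landscape generator makes every stage
verifiable without field data.

## Terrain predictors

All six layers are computed on the 3×3 Moore neighbourhood of a projected,
square-celled DEM (`ElevationGrid`), with the standard toolkit
definitions:

| layer | definition | units |
|---|---|---|
| `tri` | mean of the 8 absolute differences centre − neighbour | m |
| `tpi` | centre − mean of the 8 neighbours (negative = concave) | m |
| `roughness` | max − min over the full 3×3 window | m |
| `slope` | arctan of the gradient magnitude, Horn 8-neighbour weighted differences | ° (or rad) |
| `aspect` | azimuth of steepest descent, clockwise from grid north | ° in [0, 360) |
| `flowdir` | D8 code of the neighbour with the greatest distance-weighted drop | codes 1–128 |

Design choices a user should know:

* **Edge and missing-data policy.** Any cell whose 3×3 window touches the
  grid border or a missing cell is missing in *every* layer. No window
  shrinking: all layers therefore share one support, which is what makes
  joint extraction at points well defined.
* **Slope/aspect algorithm.** Horn's (1981) weighted differences are the
  default (the common raster default); `zevenbergenThorne = TRUE`
  switches both to the 4-neighbour central differences.
* **Flat cells.** Aspect is undefined where the gradient magnitude is
  below `flatTol = 1e-9` (rise/run) and is set missing there. The other
  five layers keep flat cells (TRI/TPI/roughness 0, slope 0, flowdir 1 by
  the tie rule).
* **Flow-direction ties and pits.** Drops are divided by the inter-cell
  distance (diagonals `cellsize * sqrt(2)`; `distanceWeighting = FALSE`
  disables this). In a pit the cell points at the smallest rise. All ties
  break to the smallest D8 code, so a perfectly flat neighbourhood yields
  1 (east) deterministically.
* **Coordinates.** Projected metric grids only; `readAsc()` rejects
  grids that look geographic (degree-sized cells), because neighbourhood
  distances in degrees would be meaningless.

The whole terrain module is cross-checked cell-for-cell against an
independent brute-force implementation that literally loops over 3×3
windows, and against closed forms on exact planes.

## The balanced resampling test

With $n_p$ presences and $n_a \gg n_p$ absences, the procedure for each
predictor is:

1. compute the observed presence mean $\bar{x}_p$;
2. draw $B$ pseudo-samples of size $n_p$ (without replacement within each
   draw) and record their means — the *null distribution of means*;
3. form the central 95% percentile interval of the null means
   (linear-interpolation sample quantiles);
4. flag the predictor, with a direction, if $\bar{x}_p$ falls outside the
   interval.

**What the pseudo-samples are drawn from matters.** Two constructions are
provided:

* `null = "pooled"` (default): draws come from presences and absences
  combined. This is a Monte-Carlo permutation test of the mean: under
  exchangeability the observed presence mean is one more draw from the
  same subset-mean distribution, so the CI-exclusion rule rejects at the
  nominal rate. Measured size at $n_p = 7$, $n_a = 37$, $B = 10{,}000$,
  $\alpha = 0.05$: ≈ 0.05 (the test suite asserts [0.035, 0.065] over
  2,000 null replicates).
* `null = "absences"`: draws come from the absences only — a balanced
  pseudo-dataset of absences per draw, the most literal reading of
  "resample as many absences as presences". We implemented this variant,
  measured it, and deliberately did **not** make it the default: its null
  distribution ignores the sampling variance of the presence mean
  ($\sigma^2/n_p$, the dominant term at $n_p = 7$) and carries a
  finite-population shrinkage, so its true type-I rate at 7 vs 37 is
  ≈ 0.12 — about 2.5× nominal. It remains available for comparability
  and its anti-conservatism is pinned by a test.

Other choices: percentile CIs use R's default type-7 (linear
interpolation) quantiles; a normal-approximation interval was considered
and rejected because the null distributions of small-subset means are
visibly lumpy; no multiple-testing correction is applied across the six
predictors by default (a Bonferroni flag exists), matching common
practice of reporting each predictor marginally; aspect (circular) and
flow direction (categorical) are averaged arithmetically by default so
that all six predictors pass through one pipeline — a circular-mean mode
for aspect exists and is the statistically coherent alternative, but note
that CI exclusion on the circle is only meaningful when the null means
stay away from the wrap point.

`runAllPredictors()` gives every predictor an independent RNG substream
derived from one master seed, so results are bit-reproducible and
per-predictor draws do not interact. `exhaustiveNull()` replaces Monte
Carlo by full subset enumeration (capped at $10^6$ subsets) and is used
as the exact oracle in the tests.

## The synthetic landscape generator

`scenario()` + `generateDem()` + `placeOccurrences()` emulate the study
system the package was built around:

* **Relief**: white noise smoothed by an isotropic Gaussian kernel
  (truncated at 4σ, computed on a padded grid so smoothing is exact and
  seed-reproducible), centred and rescaled so the sample SD equals
  `reliefSd` exactly, then tilted by a regional ramp. Defaults: 96 × 96
  cells at 10 m (≈ 1 km² of mountainside), relief SD 25 m, correlation
  length 5 cells (50 m gully-and-rib structure), ramp (0.25, 0.35) m/m —
  a strongly dissected alpine scree slope in which no cell is perfectly
  flat. On this landscape TPI is nearly uncorrelated with the other five
  predictors (|r| < 0.05, asserted in the tests), so an injected TPI
  effect cannot leak through correlation.
* **Survey**: 7 presences and 37 absences. Presence cells are drawn
  without replacement with probability ∝ `plogis(-effectBeta * z)` where
  `z` is the z-scored effect predictor (default TPI, `effectBeta = 3`),
  so presences concentrate in concave cells; absences are uniform over
  the remaining valid cells. Points sit at cell centres; no cell is used
  twice; border cells are never used.

**What the generator does *not* emulate.** Real scree physics (grain
sorting, mobility), snow transport, vegetation feedbacks — and, most
importantly for inference, the spatial structure of real surveys: real
presences cluster along transects and real absence sites are chosen by
surveyors, neither of which is random sampling. Passing calibration on
synthetic data therefore shows the procedure is correct *under random
sampling*; it does not license ignoring spatial pseudo-replication in
real data (no spatial-autocorrelation correction is implemented).

## Power: what a 7-presence study can and cannot show

Two structural facts limit end-to-end recovery rates, and both are worth
understanding before interpreting any single study:

1. **The placement mechanism saturates.** `plogis(-beta * z)` tends to an
   indicator of $z < 0$ as beta grows, so the expected presence-mean
   shift of the effect predictor is bounded by
   $E[z \mid z < 0] \approx -0.80$ SD. With $n_p = 7$ the calibrated test
   then flags TPI as lower in roughly 40–50% of replicate studies — a
   realistic reflection of how underpowered a 7-presence survey is for a
   one-predictor microhabitat effect of plausible size.
2. **Six marginal tests mean family-wise false flags.** With five
   no-effect predictors each tested at α = 0.05, some other predictor is
   flagged in ≈ 20% of replicates (slightly more than the independent
   $1 - 0.95^5$ because spatially clumped presences inflate the variance
   of presence means of autocorrelated predictors). So "exactly TPI and
   nothing else" happens in well under half of replicate studies even
   though the effect is real and the test calibrated.

The acceptance machinery reports both rates (`tpi_recovery_rate`,
`tpi_only_recovery_rate`) rather than hiding them; the
direction-of-effect property (presence mean TPI below absence mean TPI)
holds in ≈ 98% of replicates.

## IUCN criterion B2

`aoo()` counts distinct occupied cells of a 2 × 2 km occupancy grid
anchored at the coordinate origin (the IUCN guideline default) times the
cell area. Because the count depends on the anchor, the origin-shift
minimum over a 4 × 4 set of quarter-cell offsets is also reported —
AOO near a threshold should never hinge on an arbitrary grid anchor.
`eoo()` is the convex-hull (shoelace) area. `countLocations()` groups
points by single linkage with a *strict* "closer than `sepKm`" rule; the
IUCN "location" concept is threat-defined, so the separation distance is
a proxy and is always carried in the report. `criterionB2()` applies the
threshold table (CR < 10 km² and a single location; EN < 500 km² and
≤ 5 locations; VU < 2,000 km² and ≤ 10 locations; each additionally
requiring continuing decline), which assigns EN to the motivating
situation — a species occupying under 10 km² at five locations with
anticipated decline. Continuing decline is asserted by the analyst, not
inferred.

## Numerical and testing notes

* `.asc` values are written with 17 significant digits; read/write cycles
  are bit-exact, and the determinism tests compare artifacts
  byte-for-byte.
* Points map to cells by half-open intervals anchored at the lower-left
  corner, so every in-extent point belongs to exactly one cell; points on
  the top/right outer edge are out of extent.
* Monte-Carlo-vs-exact comparisons in the test suite use the
  order-statistic (distribution-free) two-SE band for quantiles, because
  subset-mean nulls of small pools are discrete and a density-based SE
  would be invalid.
* Problem sizes in the test suite were chosen to probe each property at
  full stringency where it is cheap (terrain oracles on 50 random grids;
  the three-index inequality on 10⁶ cells; calibration over 2,000 null
  replicates at B = 10,000) and at reduced size where the property is
  already pinned elsewhere.

## Known limitations

* Single-scale (3×3) neighbourhood only; no annulus/multi-scale TPI, no
  flow accumulation, no curvature.
* No reprojection: the DEM and the points must already share a projected
  metric CRS.
* The resampling test treats points as exchangeable; spatially clustered
  surveys violate this and inflate false flags (see the power section).
* Aspect's arithmetic mean is not a circular statistic; use
  `circularAspect = TRUE` when aspect matters and interpret with care.
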