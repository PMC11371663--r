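---
title: "Methods: availability-corrected niche overlap for paired taxa"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: availability-corrected niche overlap for paired taxa}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nichelegacy)
```

## The question and the model

`nichelegacy` compares the realized climatic niches of paired taxa — the
motivating design is a regionally extinct genus paired with an extant
congener of the same family — inside a shared *available* climate space.
The question is whether the pair's niches are more similar than a random
use of the available climates would produce, or detectably different: a
persistent niche difference between such pairs can be read as a climate
legacy of the extinction event.

The analysis proceeds in a fixed sequence.

1. **Climate space.** A lattice of climate cells carries V bioclim-style
   variables. A background mask delimits the climates regarded as
   available (in the motivating design, a Köppen–Geiger
   temperate-to-tropical mask; here the mask is always an input, never
   computed). A correlation-matrix PCA is fitted over the background
   cells only — each valid cell weighted once, variables centred and
   scaled to unit variance so that °C and mm are commensurable — and the
   first two components define the niche plane. Occurrences are projected
   into this plane afterwards (the "PCA-env" convention). Because the
   source description is ambiguous about whether occurrences enter the
   calibration, `fit_environmental_pca()` exposes `extra_cells` to append
   them; the background-only convention is the default and is what all
   tests exercise.
2. **Occurrences.** Records are filtered (record basis in an allowed set,
   coordinate uncertainty *strictly* below half a grid-cell width — 2250 m
   for a 2.5 arc-min grid; records with missing uncertainty are excluded
   by default, a policy switch retains them) and then downscaled: every
   record maps to the grid cell containing it and duplicate records in a
   cell collapse to one occupied cell, so each occupied cell has equal
   weight regardless of collection effort.
3. **Occupancy surfaces.** On an R×R grid spanning the background score
   ranges (expanded 5% per side), the availability density *e* is a 2D
   Gaussian KDE of the background scores and the occurrence density *o* a
   KDE of the occupied-cell scores. The corrected occupancy is
   z ∝ o/e where e is at least `availability_floor · max(e)`, and z = 0
   elsewhere; z is renormalized to sum 1. Dividing by availability makes
   z a preference surface rather than a reflection of how much of climate
   space happens to exist.
4. **Overlap and tests.** Schoener's D = 1 − ½·Σ|z₁ − z₂| measures
   overlap (0 disjoint, 1 identical). Each pair receives two directional
   randomization tests: one taxon's surface is randomized within the
   availability support B times, and the add-one estimates
   p_similarity = (1 + #{D_null ≥ D_obs})/(B+1) and
   p_difference = (1 + #{D_null ≤ D_obs})/(B+1) are reported. Across a
   study, all directional similarity p-values are adjusted together
   (Holm by default), and likewise the difference p-values; a pair is
   "similar" when at least one direction stays below α after adjustment
   (reported with the †/‡ dagger notation).
5. **Univariate profiles and volumes.** Per climate variable, the
   overlapping coefficient ∫min(f̂ₐ, f̂ᵦ) of two 1D Gaussian KDEs localizes
   which gradients separate a pair. Niche volume against the whole
   available space is estimated twice: as Schoener's D between z and the
   renormalized availability e, and as the cell-count ratio of 95%
   highest-density regions (HDR) of the taxon and background KDEs. Group
   volumes are compared by a two-tailed paired t-test and a pair-wise OLS
   regression — standard procedures included as report plumbing.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `R` | 100 | grid cells per axis | the conventional resolution for corrected occupancy grids; coarser grids blur D, finer ones slow the nulls quadratically |
| `B` | 1000 | null replicates | the motivating design's replicate count; the smallest attainable p is 1/(B+1), so studies adjusted over 2N directional tests need B ≥ 2N/α − 1 |
| bandwidth | Silverman per axis | score units | parameter-free reference rule computed on the sample being smoothed (occurrences for o, background for e) |
| `availability_floor` | 1e−6 × max(e) | — | guards o/e against blow-ups at the climate-space fringe; z is defined as 0 below it |
| `margin` | 0.05 | fraction of score range | keeps boundary mass of the KDEs on-grid |
| `max_uncertainty_m` | cell_size/2 at the equator | m | strict "<" bound; override with an explicit value (2250 m for 2.5 arc-min) when the study fixes one |
| `hdr_level` | 0.95 | probability mass | the conventional quantile for HDR niche area |
| `alpha` | 0.05 | — | applied to adjusted p-values |

## The randomization null

Two strategies are implemented; both relocate only within the
availability support and renormalize, so every null surface is a valid
occupancy distribution (this mass-preservation is property-tested).

* `"shift"` (default): translate the observed z so its centroid lands on
  a support cell drawn uniformly at random, clip to the grid, zero
  outside the support, renormalize. This preserves the observed niche
  *shape* and asks "would a niche shaped like this, placed anywhere in
  the available space, overlap this much?" — the reading we take of a
  niche "randomly generated from the available climate space".
* `"resample"`: redraw the taxon's n occupied cells from the background
  cloud and rebuild z. This is the exact null of a taxon using available
  climate at random.

The calibration experiment in the acceptance suite draws *both* taxa
from availability and checks that p-values are uniform. That experiment
uses the `"resample"` null deliberately: its null hypothesis is the
data-generating process, making observed and null D exchangeable, which
is the property uniformity tests. The shift null answers a different
(shape-conditional) question and is not expected to be calibrated
against this particular generator.

p-values use the add-one permutation estimator with ties counted as
exceedances, so p ∈ [1/(B+1), 1] and never 0.

## Numerical choices and degenerate inputs

* Densities are evaluated at grid-cell centres and treated as discrete
  masses (no quadrature weights); Schoener's D downstream is the
  discrete statistic, so Σz = Σe = 1 exactly (tolerance 1e−9).
* PCA axis signs are fixed by flipping each component so its
  largest-magnitude loading is positive — deterministic across platforms.
* Zero-variance climate variables are dropped with a warning before the
  PCA; fewer than two informative variables is an error.
* Fewer than 5 occupied cells is an error in `build_occupancy()` (the
  statistics are meaningless below that) and a structured *skip record*
  in `run_pair()`, so one data-poor taxon cannot crash a study.
* HDRs are built by sorting cell masses and accumulating to the level,
  with plateau ties all included — no density-threshold interpolation.
* Cell membership uses a half-open rule (west edge in, east edge out;
  north edge in, south edge out) so boundary points belong to exactly
  one cell; tested at the edges.
* All randomness flows through seeds passed explicitly; per-pair and
  per-stage seeds are derived from the master seed and the pair id by a
  documented hash, so re-running one pair reproduces its slice of the
  full study, and reports contain no timestamps — two runs with one
  master seed are byte-identical.

## What the synthetic generator emulates — and what it does not

`generate_climate_landscape()` builds V variables as linear mixes of
smooth latent spatial factors (an east–west and a north–south gradient,
optionally smoothed-noise fields) plus independent noise. That
reproduces the property the analysis actually relies on: strongly
inter-correlated climate variables whose variation is captured by two
PCA axes. The background mask is the central 70% quantile band of
factor 1, emulating the exclusion of an arid interior. Occurrences are
drawn with Gaussian niche weights in latent-factor space
(`sample_occurrences()`), jittered within cells, with log-normal
coordinate uncertainty (median 500 m) and a 10% missing-uncertainty
fraction so the filter's missing-value policy is always exercised.
Shifted pair scenarios separate centroids along the *last* latent factor
— the axis not truncated by the background band — so that "separated by
4× breadth" means separated niches, not niches squeezed against the mask
edge.

The generator does not emulate real geography, the true covariance of
bioclim variables, spatially structured sampling bias beyond
within-cell clustering, or coastline nodata fringes. Passing tests
therefore demonstrate that the statistics behave correctly when their
assumptions hold — not that any particular real-world dataset meets
those assumptions. The headline quantities of the motivating study
(its PCA variance fractions near 63.7%/20.3%, its per-pair D values)
require the original WorldClim + Köppen + GBIF inputs and are treated as
external validation anchors, not test fixtures.

## Problem sizes used by the test suite

Chosen as the package's own desk-scale study conditions: landscapes of
30×40 to 40×40 cells with 19 variables; 200–500 records per taxon;
B = 199 for repeated experiments (B = 1000 remains the analysis
default); 200 seeded runs for null calibration; 50 runs for power and
recovery; 20 seeds per separation step in the monotonicity sweep. The
power and calibration experiments share one landscape across runs, with
per-run randomness in the occurrence sampling and test nulls.

## Known limitations

* Fixed-bandwidth KDE only; no boundary correction or adaptive
  bandwidths, so fringe cells of the availability surface are smoothed
  outward (the availability floor hides the worst of the induced o/e
  noise).
* Two niche dimensions only; no ≥3-D occupancy grids or hypervolumes.
* No coordinate-reference-system handling: all rasters must share one
  lattice, and the uncertainty default converts degrees to metres at the
  equator.
* Hellinger-based overlap and niche-equivalency (identity) tests are out
  of scope; the difference test is the lower tail of the same null, not
  an equivalency randomization.

## A minimal worked run

```{r example, fig.width = 5, fig.height = 4}
scen <- make_pair_scenario("shifted", separation = 1, n_per_species = 300,
                           seed = 7)
grid <- scen$landscape$grid
background <- apply_background_mask(grid, scen$landscape$mask)
space <- fit_environmental_pca(background)
records <- as_occurrence_records(rbind(scen$occurrences_a,
                                       scen$occurrences_b))
report <- run_pair(pair_config("Demo", "TaxonA", "TaxonB"), records,
                   grid, background, space,
                   pair_settings(B = 199), seed = 1)
report
report$volumes
head(report$variable_overlaps[order(report$variable_overlaps$overlap), ], 3)
plot(report$tests$a)
```
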