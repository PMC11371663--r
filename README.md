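# nichelegacy

Compares the realized climatic niches of paired taxa — typically a
regionally **extinct** genus against an **extant** relative of the same
family — inside a shared available climate space, to ask whether the
extinct lineage carries a distinguishable climate-niche legacy. It is
aimed at macroecologists working with gridded climate layers
(bioclim-style variables) and occurrence records (GBIF-style tables).

## What it computes

All niche quantities live on the first two axes of a correlation-matrix
PCA fitted over the *background* climate cells (the available climate
space, delimited by a mask supplied as input). For each taxon, occurrence
records are quality-filtered, downscaled to unique grid cells, projected
into the PCA plane, and turned into an availability-corrected occupancy
surface on an R×R grid:

- availability: *e* = normalized 2D Gaussian KDE of background scores,
- occurrence density: *o* = KDE of the occupied-cell scores,
- corrected occupancy: *z* ∝ *o*/*e* on the availability support
  (zero where availability falls below a floor), renormalized to Σz = 1.

On these surfaces the package provides:

- **Schoener's D** overlap, D = 1 − ½·Σᵢ|z₁ᵢ − z₂ᵢ| ∈ [0, 1]
  (0 = disjoint niches, 1 = identical);
- **directional similarity and difference randomization tests**: one
  taxon's surface is randomized B times within the available space
  (centroid-shift null by default, occupied-cell resampling as an
  alternative), with add-one p-values
  p = (1 + #{D_null ≥ D_obs})/(B + 1) and the opposite tail, adjusted for
  multiple comparisons across the whole study (Holm) and summarized with
  the †/‡ dagger notation;
- **per-variable kernel-density overlap** (the overlapping coefficient
  ∫min(f̂ₐ, f̂ᵦ)) with per-taxon means, to localize which climate
  gradients separate a pair;
- **two niche-volume estimators** — Schoener's D of a taxon's occupancy
  against the availability surface, and the area ratio of 95%
  highest-density regions — plus a paired t-test / regression comparison
  of volumes between the extinct and extant groups;
- a **synthetic data module** (`landscape_spec()`,
  `generate_climate_landscape()`, `sample_occurrences()`,
  `make_pair_scenario()`) generating spatially structured, correlated
  climate lattices, background masks and occurrence sets from known
  Gaussian niches, so the whole pipeline is testable end-to-end with
  known truth.

File formats: ESRI ASCII grids (one per variable, plus a mask raster),
CSV/TSV occurrence tables with Darwin-Core-style columns, YAML/JSON study
configs, CSV + JSON reports.

## Worked example

```r
library(nichelegacy)

scen <- make_pair_scenario("shifted", separation = 1, n_per_species = 300,
                           seed = 7)
grid       <- scen$landscape$grid
background <- apply_background_mask(grid, scen$landscape$mask)
space      <- fit_environmental_pca(background)
records    <- as_occurrence_records(rbind(scen$occurrences_a,
                                          scen$occurrences_b))
report <- run_pair(pair_config("Demo", "TaxonA", "TaxonB"), records,
                   grid, background, space, pair_settings(B = 199),
                   seed = 1)
report
#> Pair: TaxonA vs TaxonB (Demo)
#>   Schoener's D: 0.343
#>   p similarity (a, b): 0.47 0.425
#>   p difference (a, b): 0.535 0.58
report$volumes
#>    taxon  status schoener_volume hdr_volume n_occupied_cells
#> 1 TaxonA extinct       0.5929628  0.5757049              190
#> 2 TaxonB  extant       0.5757336  0.5220470              198
```

The two niches were generated one latent-factor standard deviation
apart, twice their common breadth: the overlap D = 0.34 is intermediate,
and neither the similarity nor the difference test reaches significance
in either direction (all p ≈ 0.4–0.6) — with this effect size and 300
records per taxon the pair is neither provably similar nor provably
different. Each taxon still occupies a little over half of the available
climate space by both volume estimators. The per-variable profile
(`report$variable_overlaps`) shows the lowest overlaps (~37–43%) on the
variables loading on the shifted gradient.

For a multi-pair study, `run_study()` takes a list of `pair_config()`s,
applies the study-wide p-value adjustment, tallies similar/non-similar
pairs, compares group volumes, and `write_study_report()` emits
deterministic `report.csv`/`report.json`. The methods vignette
(`vignettes/niche-overlap-methods.Rmd`) documents the model, the null
strategies, every tunable parameter, and the generator's scope.

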