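# forestfrag

Fractal fragmentation, connectivity and heterogeneity analysis of
forest-cover change rasters.

Deforestation rarely removes forest in one tidy block: loss arrives as
patches that either extend existing clearings or open up fresh locations,
and the two regimes reshape the remaining forest very differently.
`forestfrag` quantifies that spatial structure from the standard three-layer
forest-change data model — a baseline tree-cover mask, a loss-year raster
(integer code *t* marks pixels lost in year *t*, 0 = never lost) and a
cumulative regeneration mask — using particle (patch) statistics and three
fractal indicators, with a seeded synthetic forest-change generator for
validation against exact ground truth. It is aimed at landscape ecologists
and remote-sensing analysts working with binarized, metrically projected
rasters (e.g. 30 m Landsat-derived products).

## The indicators

* **Particle analysis.** Connected-component statistics per layer and year:
  patch count, total area (ha) and average patch size, plus the number of
  loss patches appearing in *fresh locations* (components of a year's loss
  with no 8-neighbour contact with previously accumulated loss).

* **Fractal Fragmentation Index (FFI).** Box-counting dimensions of the
  area set and of its inner-boundary perimeter set on a common fixed grid,

  FFI = D_A − D_P,  D = slope of log N(ε) vs log(1/ε).

  Compact objects score near 1 (a filled region has D_A = 2 and an
  essentially one-dimensional boundary); fragmented ones near 0, and a
  single pixel exactly 0 (its perimeter set *is* its area set).

* **Local Connected Fractal Dimension (LCFD).** At each foreground pixel,
  the mass M(ε) of the 8-connected component containing the pixel is
  counted inside windows of growing odd side ε centred on it; the LCFD is
  the slope of log M(ε) vs log ε (the regression form of M(ε) ∝ F·ε^LCFD).
  It is exactly 1 on a straight one-pixel line and exactly 2 inside a
  filled region, and maps local connectivity pixel by pixel.

* **Lacunarity Λ(r).** The normalized second moment of fixed-grid box
  occupancies p(r,i),

  Λ(r) = N(r) · Σᵢ p(r,i)² / (Σᵢ p(r,i))²,

  with N(r) the total number of grid boxes. Λ ≥ 1 always; translation-
  invariant cover gives 1, mass confined to one of N boxes gives N. A
  randomized Tug-of-War (AMS) sketch of the second moment Σp² is available
  for streaming-scale inputs, with exact computation as the default.

* **Reporting.** `run_timeseries()` derives per-year tree-cover, yearly-loss
  and cumulative-loss masks, computes all metrics per layer and year,
  min–max standardizes each series onto [0, 1]
  ((V − Vmin)/(Vmax − Vmin)), and assembles the Spearman rank-correlation
  matrix of the metric series.

## Worked example

```r
library(forestfrag)

# a synthetic 128x128, 14-year scenario with known ground truth
scn <- generate_scenario(scenario_config(seed = 1))
rep <- run_timeseries(scn$layers, timeseries_config(seed = 1))
subset(rep$report, layer == "tree_cover" & metric == "ffi")
```

Running the numbered drivers reproduces the full workflow and prints, for
seed 1:

```
tree cover: 878.9 -> 823.6 ha (-6.3% change)
tree-cover FFI: 0.676 -> 0.474 (fragmentation increased)
cumulative-loss lacunarity aggregate: 69.58 -> 7.50
```

i.e. a 6.3% loss of cover carries a much larger drop in the fragmentation
index (the remaining forest becomes more perforated than its area change
suggests), while the lacunarity of the accumulating loss pattern falls as
loss spreads from one concentrated cluster towards many locations.
`analysis/04_regimes.R` contrasts the two pure regimes over 20 replicates:
scattered loss (clustering probability 0) erodes the tree-cover FFI faster
(mean drop 0.231 vs 0.143), while compact loss yields the higher aggregate
lacunarity (13.53 vs 7.96) because Λ is a concentration functional.

The workflow scripts, in order:

| script | writes |
| --- | --- |
| `analysis/01_fixtures.R` | `results/fixture_anchors.csv` — analytic anchors |
| `analysis/02_simulate.R` | `results/scenario/` — layers + ground truth |
| `analysis/03_timeseries.R` | `results/report/` — long table, Spearman matrix |
| `analysis/04_regimes.R` | `results/regime_comparison.csv` |

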