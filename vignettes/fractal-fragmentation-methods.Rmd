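---
title: "Fractal fragmentation metrics for forest-change rasters: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fractal fragmentation metrics for forest-change rasters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(forestfrag)
```

`forestfrag` measures how forest loss reshapes a landscape, from binary
rasters of the three-layer forest-change data model: baseline tree cover,
a loss-year code layer, and cumulative regeneration. This vignette records
the models behind each metric, the tunable parameters and their defaults,
what the synthetic generator does and does not emulate, and the numerical
and design choices made where the problem left them open.

## Data model and conventions

All rasters are integer matrices with row 1 at the top and `x[row, col]`
indexing; a single `pixel_size_m` (default 30 m, the resolution of
Landsat-derived forest-change products) converts pixel counts to hectares
(1 px = `pixel_size_m`² / 10⁴ ha; 0.09 ha at 30 m). Inputs are assumed to
be in a metric projection already: the package deliberately carries no
coordinate system and performs no reprojection, which keeps it free of GIS
dependencies. TIFF I/O (`read_raster`/`write_raster`) is bit-exact for
masks and small-integer grids; because plain TIFF containers written here
carry no georeferencing, the pixel size travels as an explicit argument
rather than being read from file tags.

Per-year masks derive from the layer stack as: `loss_t` = pixels with code
`t`; `cumulative_loss_t` = codes 1..t; `tree_cover_t` = baseline cover
minus cumulative loss. Gain is analyzed once, as the cumulative layer it
is, and never re-added to yearly cover — so the cover series is monotone
by construction, matching how cumulative regeneration layers are published
(a single
period-total image, not yearly ones).

## Particle statistics

Patches are connected components of a mask; the default adjacency is
8-connectivity, consistent with the 8-neighbour rule used by the local
connected dimension, with 4-connectivity exposed as an option. "New
independent" loss is operationalized as: a connected component of the
current year's loss whose 1-pixel (Chebyshev) dilation does not intersect
the previously accumulated loss. Adjacency-by-one-pixel is the weakest
notion of "extending an existing clearing" and makes the complementary
count — fresh-location patches — well defined without a size threshold.

## Box counting and the Fractal Fragmentation Index

`box_count()` covers the image with a fixed non-overlapping grid anchored
at the top-left corner, includes partial boxes at the right/bottom edges,
and fits log N(ε) against log(1/ε) by OLS; `r_squared` is reported so
degraded fits are visible. Grid-offset averaging (multiple grid origins)
is deliberately omitted: it changes counts by at most the boundary-box
count (a property the tests assert as a sanity bound) and would make the
counts non-deterministic unless all offsets are enumerated.

FFI = D_A − D_P with both dimensions counted on identical grids and scale
sets, and the perimeter defined as the 4-neighbour inner boundary (a
foreground pixel with a background or out-of-image 4-neighbour). The
4-neighbour definition makes the single-pixel identity exact: such an
object equals its own perimeter set, hence FFI = 0.

Default scales are dyadic from 2 up to **min(H, W)/8**, extended toward
min/2 only when fewer than three dyadic scales would otherwise fit, and
ε = 1 is always excluded (N(1) is the raw pixel count and dominates the
fit). The cap is deliberately lower than the largest boxes that would
physically fit: a box of half the image side contributes ~4 counts, sits
far from the ε→0 regime that defines the dimension, and measurably biases
the perimeter slope upward — on a filled 256×256 square, capping at
min/2 gives D_P = 1.14 (FFI 0.86) whereas capping at min/8 gives
D_P = 1.04 (FFI 0.96), against the ideal D_P = 1. Scale sets are always
user-overridable per call.

## Local Connected Fractal Dimension

At a foreground seed pixel, `connected_mass()` counts the 8-connected
component containing the seed *within* the ε×ε window centred on it
(connectivity evaluated only among in-window pixels; windows clipped at
image borders). The phrase "connected with eight neighbours" is read as
the standard Moore neighbourhood; the alternative literal reading of an
"8×8 environment" is internally inconsistent (an even window has no
centre) and is rejected. The LCFD is the OLS slope of log M(ε) on log ε —
the regression form of M(ε) ∝ F·ε^LCFD, with log F the intercept.

Defaults: odd ε from 3 to 33 for pixel-level work; the time-series
pipeline uses 3 to 21 to keep full-map computation fast at typical scene
sizes (the map visits every foreground pixel and runs one bounded
flood-fill per scale, implemented in C++). Two border policies exist
because two uses conflict: maps are computed for *every* foreground pixel
with clipped windows (`"clip"`), while the per-layer scalar defaults to
`"exclude"` — pixels whose largest window would be clipped are left out of
the mean — because that makes the analytic anchors exact: a full-width
line then averages exactly 1 and a filled image exactly 2. The per-year
scalar is the arithmetic mean over counted foreground pixels; the full
histogram is returned alongside for anyone preferring mode or median.

Slopes at anchor fixtures lie in [0, 2], but on arbitrary masks the OLS
slope may exceed 2 (when a cluster disconnected at small ε merges into
the seed's component at larger ε, M jumps), so no global [0, 2] clamp is
applied; values are reported as fitted.

## Lacunarity and the Tug-of-War sketch

`exact_lacunarity()` computes Λ(r) = N(r)·Σp²/(Σp)² over the same fixed
grid as box counting, with N(r) counting **all** grid boxes including
empty ones ("total number of boxes"); an occupied-only convention exists
in parts of the literature but cannot be attributed to any fixed
reference implementation, so the total-box convention is the default and
the occupancy vector is returned raw for anyone needing the alternative.
Λ ≥ 1 by Cauchy–Schwarz, with equality for translation-invariant cover at
divisor scales, and maximum N under confinement to one box.

Λ is therefore a *concentration* functional: for fixed total mass,
concentrating occupancy raises Σp². One consequence worth stating
explicitly, because intuition about "scattered = heterogeneous" points
the other way: splitting a compact square into equal-area well-separated
small squares *lowers* the aggregate Λ (17.05 → 16.44 for a 12×12 square
vs nine 4×4 squares on a 64×64 grid), and in the synthetic regime
comparison the compact-growth regime shows the higher cumulative-loss
lacunarity. High Λ flags gappy, clumped occupation — not many scattered
fragments.

The Tug-of-War estimator approximates Z² = Σp² by the median over s2
groups of means over s1 replicates of (Σᵢ σᵢ pᵢ)², with i.i.d. Rademacher
signs σᵢ — the classic second-frequency-moment sketch. It is unbiased,
and its single-replicate relative standard deviation is
√2·√(1 − Σp⁴/Z⁴) ≈ 1.4 for many-box vectors, so a practical relative
error of a few percent needs s1 in the thousands (s1 = 2000, s2 = 5 gives
≈2.5%); the exact computation is the default and the sketch exists for
inputs too large to hold occupancy vectors exactly, and for fidelity to
the method family's name. Every sketch call takes an explicit seed and is
reproducible.

The per-layer scalar is the arithmetic mean of Λ(r) over dyadic r from 2
to min(H, W)/4; the full profile is always emitted alongside, since a
single number necessarily hides the scale dependence.

## Standardization and correlation

Metric series are min–max standardized, (V − Vmin)/(Vmax − Vmin), per
(layer, metric) across years, so endpoints are attained exactly. A
constant series returns zeros with a logged warning rather than an error,
so batch reporting over degenerate runs (e.g. a scenario with no loss in
some layer) completes. Spearman's rank correlation is computed over all
complete, non-constant yearly series; coefficients only, no p-values, as
the association table is descriptive.

## The synthetic generator

`generate_scenario()` emulates the structure, not the ecology, of a
forest-change stack:

* **Baseline cover** thresholds smoothed Gaussian noise (three passes of a
  separable moving average) at the quantile matching `cover_fraction`,
  giving spatially coherent, blobby cover rather than salt-and-pepper.
* **Loss patches** grow as connected blobs by random frontier accretion
  inside remaining cover, to sizes drawn from a log-normal (default
  meanlog = log 12, sdlog = 0.7 in pixels ≈ 1 ha mean at 30 m, the size
  regime of reported loss sites). With probability `clustering_prob` a
  patch seeds 8-adjacent to prior-year loss; otherwise at a fresh location
  at least `min_gap` (default 3) pixels from any prior loss.
* **Exact truth.** Same-year patches are forbidden from touching each
  other (a 1-pixel blocked margin), so each year's placements *are* the
  connected components of that year's loss mask: patch counts, pixel
  areas and fresh-location flags recorded at generation are exact, and the
  particle module must recover them identically — a recovery the tests
  assert with no tolerance.
* **Gain** is a uniform random subset of cumulative loss at
  `gain_fraction` (default 0.15), matching the published practice of one
  cumulative regeneration layer per period.

Defaults (128×128 px, 14 years, 4 patches/year, cover 0.6,
clustering 0.5) describe a ~1,475 ha scene losing a few percent of cover
over the record. What the generator does **not** emulate: terrain and
accessibility gradients, spatially correlated loss risk, sensor noise and
misregistration, partial-canopy pixels. Tests passing on these scenarios
therefore validate the *metrics and bookkeeping*, not any ecological
claim about real landscapes.

All randomness goes through R's generator scoped with `withr::with_seed`;
every stochastic operation takes an explicit seed and identical seeds give
bit-identical outputs.

## Problem sizes and determinism

The shipped analyses use 96–128 px scenes, 4–14 years and 20 replicates
per regime — sizes chosen so the full workflow and test suite run in
seconds to a couple of minutes on one core while leaving every qualitative
contrast (regime directions, truth recovery, oracle equivalence) clearly
resolved; all metrics scale to larger rasters, with the LCFD map the only
super-linear step (pixels × scales × window area).

## Known limitations

* No georeferencing: inputs must already share extent, grid and metric
  projection; the pipeline refuses mixed shapes but cannot detect mixed
  projections.
* Box-counting and lacunarity use a single top-left-anchored grid;
  counts shift slightly under translation (bounded by the boundary-box
  count), which matters only for very small objects.
* The FFI is a whole-image index; it says nothing about where
  fragmentation happens (the LCFD map fills that gap).
* Fixed-grid (non-gliding) lacunarity only; gliding-box variants weight
  scales differently and are out of scope.
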