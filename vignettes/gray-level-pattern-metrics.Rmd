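---
title: "Gray-level pattern metrics: model, conventions and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gray-level pattern metrics: model, conventions and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(grayscape)
```

## The measurement model

`grayscape` treats landscape pattern as a pixel-level, spatially continuous
property. Every analysis region — a square moving window or the whole map —
is summarized by at most two tabulations of its integer gray levels
(0–100):

* **Frequency tabulation.** Counts `x(i)` per gray level, with proportions
  `p(i)`, the number of occupied levels `Ng`, mean `μ`, and population
  variance `σ²`. First-order metrics (mean, median, majority, range,
  Shannon and Gini–Simpson diversity/evenness, SD, CV, RMS, mean absolute
  deviation, skewness, kurtosis, focal area density, the mosaic
  composition) are functions of this distribution only; they ignore the
  spatial arrangement inside the region.
* **Adjacency tabulation.** The ordered co-occurrence matrix `x(i,j)`
  under the 2-neighbor rule: each pixel contributes at most two pairs, one
  with the pixel below and one with the pixel to the right, each counted
  once, the upper/left member indexing the row. (A full `R × C` region
  therefore holds `R(C−1) + C(R−1)` pairs — 24 for a 4 × 4 map.) The
  unordered matrix folds this across the diagonal
  (`x'(i,j) = x(i,j) + x(j,i)`, `i ≠ j`). Second-order metrics are
  functions of `p(i,j)`, its marginals, or the difference/sum
  distributions `p_{x−y}`, `p_{x+y}`; they respond to spatial arrangement
  (contagion, texture) at lag one.

The same formulas apply to nominal (categorical) and ordinal (quantized
numeric) maps, but not all are *meaningful* for both: the registry
(`gsc_metrics()$input_type`) flags each metric as applicable to all data
(`A`), nominal only (`N`, the mosaics), or ordinal only (`O`, anything
using the numeric magnitude of the levels, e.g. mean, contrast,
correlation). Kurtosis is flagged ordinal-only: a fourth central moment
has no interpretation for unordered class codes. The package computes
whatever it is asked to; the flag is guidance, not a gate, since a
knowledgeable user may have reasons (e.g. treating ordinal data as
nominal).

### Assumptions

* Pixels are square and the neighbor lag is one pixel; no diagonal
  neighbors, no distance- or angle-resolved co-occurrence.
* Gray levels are a closed vocabulary, 0–100. Numeric data must be
  quantized first (`gsc_quantize()`): equal-width bins over a stated
  source range, at most 101 bins, top bin closed. Quantization is an
  explicit modelling step — the bin count sets the gray-level resolution
  every metric sees, and results are comparable only across maps
  quantized the same way.
* Missing data are absent, not zero: a missing pixel contributes to no
  tabulation, and an adjacency is dropped if *either* member is missing
  (the surviving member still counts in the frequency tabulation).

## Tunable parameters

| parameter | units | default | notes |
|---|---|---|---|
| `window` | pixels (odd side length) | none (required) | sets the observation scale; the ground area is `(side × resolution)²` (`gsc_window_area()`) |
| `exclude_zero` | flag | `FALSE` | treats gray level 0 as missing everywhere; for maps where 0 is background rather than measurement |
| `t1`, `t2` | gray level | none | targets of the focal metrics (21–24) |
| `kstar` | difference level 0–100 | none | cut-off of the k-contagion cumulative sum; larger `kstar` counts blurrier adjacencies as "similar", and the metric is non-decreasing in it |
| `n_bins` | count (2–101) | 101 | quantization resolution |
| scalogram `sides` | pixels | 5, 7, …, 45 (21 scales) | the conventional multi-scale grid; any odd sides work |
| scalogram `summary` | — | `max` | reduction of each per-scale map (`max`, `mean`, `quantile`) |

## Numerical conventions

These are the choices a re-implementation must match to reproduce values
exactly:

* **Logarithms** are natural throughout. Evenness normalizers
  (`log Ng`, `2 log Ng`, `log(Ng²+Ng) − log 2`, `log Nk`) cancel the base;
  raw entropies do not, so one fixed base matters.
* **Guards produce missing, not errors**: `Ng > 1` for the evenness and
  equitability family, `Nk > 1` for difference/sum evenness, `μ > 0` for
  CV, `σ > 0` for skewness/kurtosis, `σ_x σ_y > 0` for correlation, window
  (or global) gray-level range `> 0` for the range-normalized similarity
  metrics, composition summing to 1 for the mosaics, nonzero row mass for
  the conditional focal adjacency, and a nonempty tabulation for
  everything. An empty window is nodata.
* **Median** with an even pixel count returns the lower middle order
  statistic, keeping the output an integer gray level. **Majority** ties
  resolve to the smallest tied level — deterministic and independent of
  traversal order.
* **Standard deviation** (metric 25) and **RMS** (metric 47) carry their
  square roots; SD is the population estimator (divisor `n`), consistent
  with `σ²` above.
* Bounded metrics are **clamped** to their declared interval to absorb
  last-bit floating-point overshoot (an evenness can otherwise come out at
  `1 + 2·10⁻¹⁶`); the clamp never moves a value by more than that.
* **Sum entropy** carries no published bound and is treated as an
  unbounded real (so it is ineligible for byte output).
* The **global range** used by `SimilarityRGlobal` is computed once from
  the whole input map (under the same zero policy) before windowing.

### The moving-window engine

The engine maintains the dense 101-slot count vector and 101 × 101 count
matrix incrementally: moving the window one column right subtracts the
leaving column's pixels, its vertical pairs and its horizontal pairs into
the next column, then adds the entering column's. Counts are integers, so
there is no floating-point drift, and derived statistics are recomputed
from counts per window; the output is therefore *identical* (not merely
close) to rebuilding every window from scratch, which the test suite
asserts over random maps with missing pixels
(`engine = "rebuild"` exposes the scratch path). The output depends only
on the inputs — any future parallel partitioning must reproduce it
bit-for-bit.

**Edge behavior:** windows overhanging the map shrink to their in-bounds
pixels rather than emitting a nodata border. This keeps a value at every
input pixel (the output preserves the input extent and resolution) at the
cost of a smaller sample behind edge values. Other tools may pad or blank
edges; comparisons near edges should be made with that in mind.

## The mosaic partitions

The two mosaic metrics classify the composition `(p(1), p(2), p(3))` of a
3-class map. The package's partitions are:

* **19-class:** the three corner classes where one proportion is exactly 1,
  plus the 16 regions induced by the 10% ("present") and 60% ("dominant")
  thresholds on each axis. Six threshold lines cut the simplex into
  exactly 16 regions (no three lines meet inside it), so with corners the
  partition has 19 cells; the class *counts* thus pin down the geometry
  even though code numbering schemes vary between products. Codes run
  corners (1–3), dominant-axis classes (4–15, four per axis by which of
  the other two are present), then the four no-dominant classes (16–19).
* **103-class:** the three corners plus the 100 triangular cells (55
  upward, 45 downward) of the 10-percent mesh of the simplex.

Threshold comparisons use a 10⁻⁹ tolerance, and mesh coordinates within
10⁻⁷ of an integer are snapped before flooring, so grid-aligned
compositions (the common case: window proportions are rationals) land
deterministically; compositions on a mesh vertex fold into the adjacent
upward cell with the largest coordinate decremented. Both partitions are
total and single-valued on the valid simplex — enumeration tests confirm
exactly 19 and 103 distinct codes and axis-permutation symmetry of the
19-class structure. Because published mosaic products number their classes
differently, `gsc_mosaic_legend()` (and the legend file written beside any
mosaic map) is the authoritative decoder for this package's codes; users
comparing against another product should map via composition descriptors,
not via raw code numbers.

## Input/output conventions

Gray-level rasters read from 8-bit single-band TIFF or headerless 8-bit
binary (row-major, explicit dimensions); byte 255 is the missing code —
outside the gray-level range, and the conventional byte nodata. Metric
maps write as 32-bit float TIFF with NaN nodata; the float writer emits a
minimal uncompressed baseline TIFF (IEEE-float sample format) directly,
because the general-purpose TIFF binding available to R stores float
samples only on [0, 1] while many metrics are unbounded. Byte output
stores `round(100·v)` for [0, 1]-bounded metrics and `round(v)` for
[0, 100]-bounded/integer metrics and mosaic codes, with 255 as nodata;
unbounded metrics — and correlation, whose range includes negatives —
refuse byte mode. Georeferencing tags are not carried; outputs align
cell-for-cell with inputs, so the input's world metadata applies
unchanged.

## The synthetic generator and what tests show

`gsc_fixture()` generates the test universe: constants, checkerboards,
gradients, i.i.d. categorical fields, smooth sinusoidal surfaces quantized
to gray levels ("binned"), and random rectangular patch mosaics
("blocks"), each optionally thinned by missing pixels, all reproducible
from a seed. These span the structural extremes the metrics respond to —
no structure, maximal alternation, monotone trend, pure noise, smooth
autocorrelation, and patchiness — plus the degenerate cases (single level,
all missing, zero-heavy maps) that exercise every guard.

What they do not emulate: real land-cover maps' long-range anisotropic
structure, mixed-resolution artifacts, class-imbalance typical of rare
habitats, or georeferencing. Passing tests therefore certify the
*arithmetic* — that every metric equals its definition (engine vs.
independent brute-force oracle to 10⁻⁹ relative, across all 51 metrics,
with and without missing pixels and zero exclusion) and that the window
machinery is exact — not that any metric is ecologically apt for a given
real landscape.

Test problem sizes are chosen to exercise every code path at desk scale:
oracle comparisons on ~10 × 10 regions (the oracle is deliberately
quadratic-ish and slow), incremental-vs-scratch equivalence on 40 × 40
maps at window 7 for a representative metric of each family, enumeration
of both mosaic grids at steps 0.01/0.005, and scalograms on ~20 × 20
maps. The engine itself has no size-dependent logic, so correctness at
these sizes transfers; throughput on large maps is a separate concern
(the incremental update makes cost per pixel O(window side), not
O(window area), for the tabulation step).

## Known limitations

* Lag-one rook adjacency only; no 8-neighbor, distance-lagged or
  angle-resolved co-occurrence.
* No patch-based metrics (area, perimeter, shape) and no surface-metrology
  metrics; this package covers the frequency/adjacency family.
* Single-band, in-memory rasters; no reprojection, resampling or tiling of
  maps larger than memory.
* Mosaic code numbering is canonical to this package (see above).
* The serial engine is pure R; it favors exactness and verifiability over
  raw speed.
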