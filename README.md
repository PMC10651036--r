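# grayscape

Gray-level landscape pattern metrics on raster maps.

Landscape ecologists quantify the composition and configuration of
landscapes from raster maps. Most classic software targets the
patch–corridor–matrix view of categorical maps; maps of *numeric* features
(greenness, percent vegetation cover) call for the landscape-gradient view,
where pattern is a continuous, pixel-level property. `grayscape` serves both:
it computes **51 first- and second-order pattern metrics** — diversity,
evenness and contagion indices from landscape ecology alongside gray-level
co-occurrence (Haralick-type) texture metrics from image processing — on any
single-band raster whose pixels are integer *gray levels* in [0, 100]. A
categorical map uses its class codes directly; a numeric map is first
quantized ("binned") onto gray levels.

## The model

Within an analysis region (a moving window or the whole map extent), two
tabulations are built:

- the **frequency distribution** of gray levels: counts `x(i)` with
  proportions `p(i) = x(i)/Σx`, mean `μ = Σ i·p(i)`, variance
  `σ² = Σ (i−μ)²·p(i)`;
- the **adjacency (co-occurrence) matrix** under a 2-neighbor rule: each
  pixel is paired once with the pixel *below* and the pixel *to the right*,
  giving ordered counts `x(i,j)` (upper/left pixel = row). Folding across
  the main diagonal gives the unordered counts
  `x'(i,j) = x(i,j) + x(j,i)` (i ≠ j). Derived from `p(i,j)` are the
  marginals `p_x, p_y` with moments `μ_x, μ_y, σ_x², σ_y²` and the
  difference and sum distributions `p_{x−y}(k)` (k = |i−j|) and
  `p_{x+y}(k)` (k = i+j).

First-order metrics (mean, median, Shannon/Gini–Simpson diversity and
evenness, moments) are functions of `p(i)`; second-order metrics (entropy,
uniformity, contrast, homogeneity, correlation, cluster shade/prominence,
difference/sum entropy, contagion and targeted focal adjacencies) are
functions of the adjacency matrix. All entropies use the natural logarithm.
Two ternary **landscape-mosaic** classifiers map the composition
`(p(1), p(2), p(3))` of a 3-class map to a nominal mosaic code (19-class
partition by 10%/60% dominance thresholds, or a fine 103-class partition by
10%-step bins of the composition simplex).

In **moving-window mode** the engine slides an odd-sided square window one
pixel at a time, maintaining the tabulations incrementally (entering window
columns add their pixel and pair counts, leaving columns subtract theirs),
and writes each window's metric at its center pixel — a continuous metric
map at the input resolution. Windows overhanging the edge shrink to the
in-bounds pixels. **Global mode** evaluates one value on the whole extent.
Gray level 0 can optionally be excluded from all tabulations (a common
background/no-data convention), and a guard failure (e.g. evenness with a
single gray level) yields nodata, never an error.

## Worked example

```r
library(grayscape)

r <- gsc_fixture("binned", 60, 60, levels = 0:100, seed = 7)  # smooth surface,
print(r)                                                      # quantized
#> <gsc_raster> 60 x 60 gray-level raster
#>   gray levels : [0, 100], 101 distinct
#>   missing     : 0 / 3600 cells (code 255 on file)

gsc_global(r, "GSDiversity")
#> metric: 10
#> name: GSDiversity
#> exclude_zero: false
#> parameters: none
#> value: 0.985656327160494

m <- gsc_moving_window(r, "GSDiversity", window = 11)
print(m)
#> <gsc_map> metric 10 (GSDiversity), window 11x11
#>   60 x 60 cells, 0 nodata
#>   value range: [0.86685, 0.980398]

gsc_scalogram(r, "GSDiversity", sides = c(5, 9, 13, 17, 21))
#>   side     value
#> 1    5 0.9600000
#> 2    9 0.9769852
#> 3   13 0.9820384
#> 4   17 0.9840093
#> 5   21 0.9846515
```

The global Gini–Simpson diversity (0.986) says the map's gray levels are
close to evenly used over the whole extent; the 11×11 metric map shows where
local diversity dips (down to 0.867 in the smoothest patches). The scalogram
— here the *maximum* diversity over all windows per window size — rises and
then flattens with scale; a plateau suggests a scale domain over which
pattern–process relationships may be stable. `gsc_window_area(31, 2430)`
converts a window size to ground area (≈ 5675 km² for a 31×31 window of
2430 m pixels) when reporting observation scales.

File I/O: `gsc_read_raster()` reads single-band 8-bit TIFF (nodata byte
255) or headerless 8-bit binary; `gsc_write_map()` writes metric maps as
32-bit float TIFF (nodata NaN) or byte-scaled 8-bit TIFF (values in [0, 1]
stored as `round(100·v)`, nodata 255; unbounded metrics refuse byte mode).
A command line fronts the same functions:

```sh
Rscript inst/cli/grayscape.R --input cover.tif --output div.tif \
    --metric GSDiversity --mode moving --window 11
```

Every metric is verified against `gsc_oracle()`, an independent brute-force
transcription of the definitions over explicitly enumerated pixel and
neighbor-pair lists, and the incremental window engine is verified
bit-for-bit against per-window scratch rebuilds.

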