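# Shared test helpers: deterministic target parameters per metric and an
# engine-vs-oracle comparator with missing-value-aware relative error.

# Target parameters for metrics that need them, drawn from the raster's
# own gray levels so the targeted metrics are exercised, not vacuous.
gsc_test_params <- function(id, raster) {
  lv <- sort(unique(raster$values[!is.na(raster$values)]))
  if (length(lv) == 0L) lv <- 0L
  t1 <- if (id %in% 21:24) lv[1L] else NULL
  t2 <- if (id %in% 23:24) lv[min(2L, length(lv))] else NULL
  kstar <- if (id == 49L) as.integer(min(100L, diff(range(lv)) %/% 2L)) else NULL
  list(t1 = t1, t2 = t2, kstar = kstar)
}

# NA-aware relative discrepancy: both missing -> 0, one missing -> Inf.
gsc_rel_diff <- function(a, b) {
  if (is.na(a) && is.na(b)) return(0)
  if (is.na(a) || is.na(b)) return(Inf)
  abs(a - b) / max(1, abs(b))
}

# Max discrepancy between whole-extent engine evaluation and the
# brute-force oracle across a set of metric ids.
gsc_engine_vs_oracle <- function(raster, ids = 1:51, exclude_zero = FALSE) {
  worst <- 0
  for (id in ids) {
    ps <- gsc_test_params(id, raster)
    e <- gsc_global(raster, id, exclude_zero = exclude_zero,
                    t1 = ps$t1, t2 = ps$t2, kstar = ps$kstar)$value
    o <- gsc_oracle(raster, id, exclude_zero = exclude_zero,
                    t1 = ps$t1, t2 = ps$t2, kstar = ps$kstar)
    worst <- max(worst, gsc_rel_diff(e, o))
  }
  worst
}
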