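#' Gray-level raster
#'
#' The single map currency of the package: a 2D grid of integer gray levels
#' in \[0, 100\], with missing cells stored as `NA`. On 8-bit file I/O the
#' missing cells are coded with `missing_code` (255 by default, the
#' conventional byte nodata, which lies outside the gray-level range).
#'
#' Nominal (categorical) maps may use any integer levels in \[0, 100\];
#' numeric maps must first be quantized with [gsc_quantize()].
#'
#' @param values integer matrix; `NA` marks missing cells. Values equal to
#'   `missing_code` are converted to `NA`.
#' @param missing_code reserved integer outside \[0, 100\] used for missing
#'   data in 8-bit files. Default 255.
#' @return An object of class `gsc_raster`: a list with elements `values`
#'   (integer matrix with `NA` for missing) and `missing_code`.
#' @examples
#' r <- gsc_raster(matrix(0:15, 4, 4))
#' summary(r)
#' @export
gsc_raster <- function(values, missing_code = 255L) {
  if (!is.matrix(values)) stop("`values` must be a matrix")
  if (nrow(values) < 1L || ncol(values) < 1L) stop("raster must be at least 1x1")
  missing_code <- as.integer(missing_code)
  if (missing_code >= 0L && missing_code <= 100L)
    stop("`missing_code` must lie outside [0, 100]")
  v <- values
  if (!is.integer(v)) {
    if (any(abs(v - round(v)) > 1e-9, na.rm = TRUE))
      stop("gray levels must be integers; quantize numeric data with gsc_quantize()")
    storage.mode(v) <- "integer"
  }
  v[!is.na(v) & v == missing_code] <- NA_integer_
  bad <- which(!is.na(v) & (v < 0L | v > 100L))
  if (length(bad)) {
    rc <- arrayInd(bad[1L], dim(v))
    stop(sprintf("gray level %d at cell (%d, %d) outside [0, 100]",
                 v[bad[1L]], rc[1L], rc[2L]))
  }
  structure(list(values = v, missing_code = missing_code), class = "gsc_raster")
}

#' @export
as.matrix.gsc_raster <- function(x, ...) x$values

#' @export
dim.gsc_raster <- function(x) dim(x$values)

#' @export
print.gsc_raster <- function(x, ...) {
  v <- x$values
  cat(sprintf("<gsc_raster> %d x %d gray-level raster\n", nrow(v), ncol(v)))
  s <- gsc_validate(x)
  cat(sprintf("  gray levels : %s\n",
              if (s$n_valid == 0L) "none (all missing)"
              else sprintf("[%d, %d], %d distinct", s$min_level, s$max_level,
                           s$n_levels)))
  cat(sprintf("  missing     : %d / %d cells (code %d on file)\n",
              s$n_missing, s$n_cells, x$missing_code))
  invisible(x)
}

#' @export
summary.gsc_raster <- function(object, ...) {
  rep <- gsc_validate(object)
  class(rep) <- "summary.gsc_raster"
  rep
}

#' @export
print.summary.gsc_raster <- function(x, ...) {
  cat("Gray-level raster validation report\n")
  cat(sprintf("  cells      : %d (%d x %d)\n", x$n_cells, x$n_rows, x$n_cols))
  cat(sprintf("  valid      : %d\n", x$n_valid))
  cat(sprintf("  missing    : %d (%.1f%%)\n", x$n_missing,
              100 * x$n_missing / x$n_cells))
  if (x$n_valid > 0L) {
    cat(sprintf("  level range: [%d, %d]\n", x$min_level, x$max_level))
    cat(sprintf("  levels used: %d\n", x$n_levels))
  }
  invisible(x)
}

#' Validate a gray-level raster
#'
#' Reports the pixel counts, missing fraction and gray-level range of a
#' raster. Never raises: the constructor enforces the invariants, this
#' operation only summarizes.
#'
#' @param raster a [gsc_raster()]
#' @return list with `n_rows`, `n_cols`, `n_cells`, `n_valid`, `n_missing`,
#'   `min_level`, `max_level` (`NA` when all cells are missing) and
#'   `n_levels` (distinct gray levels present).
#' @export
gsc_validate <- function(raster) {
  stopifnot(inherits(raster, "gsc_raster"))
  v <- raster$values
  ok <- !is.na(v)
  list(n_rows = nrow(v), n_cols = ncol(v), n_cells = length(v),
       n_valid = sum(ok), n_missing = sum(!ok),
       min_level = if (any(ok)) min(v[ok]) else NA_integer_,
       max_level = if (any(ok)) max(v[ok]) else NA_integer_,
       n_levels = length(unique(v[ok])))
}

#' Quantize a numeric raster into gray levels
#'
#' Maps a numeric (gradient) raster onto integer gray levels by equal-width
#' binning of `source_range` into `n_bins` bins, producing levels
#' `0 .. n_bins - 1` (at most \[0, 100\]). The top bin is closed: a value
#' equal to the range maximum falls in the highest bin. The mapping is
#' monotone non-decreasing, and quantization is explicit -- integer maps
#' already in \[0, 100\] are taken as-is by [gsc_raster()].
#'
#' @param x numeric matrix; `NA` marks missing cells.
#' @param source_range length-2 numeric, the closed interval the data live
#'   on. Values outside it are an error (quantization never clips silently).
#' @param n_bins number of gray levels to produce, between 2 and 101.
#' @param missing_code passed to [gsc_raster()].
#' @return a [gsc_raster()] with levels in `0 .. n_bins - 1`.
#' @examples
#' cover <- matrix(runif(100), 10, 10)          # fractional cover in [0,1]
#' g <- gsc_quantize(cover, c(0, 1), n_bins = 101)
#' @export
gsc_quantize <- function(x, source_range, n_bins = 101L, missing_code = 255L) {
  if (!is.matrix(x)) stop("`x` must be a matrix")
  if (length(source_range) != 2L || !is.finite(source_range[1L]) ||
      !is.finite(source_range[2L]))
    stop("`source_range` must be two finite numbers")
  lo <- source_range[1L]; hi <- source_range[2L]
  if (!(hi > lo)) stop("`source_range` must have positive width")
  n_bins <- as.integer(n_bins)
  if (n_bins < 2L) stop("`n_bins` must be at least 2")
  if (n_bins > 101L) stop("`n_bins` must be at most 101 (gray levels span [0, 100])")
  bad <- which(!is.na(x) & (x < lo | x > hi))
  if (length(bad)) {
    rc <- arrayInd(bad[1L], dim(x))
    stop(sprintf("value %g at cell (%d, %d) outside source_range [%g, %g]",
                 x[bad[1L]], rc[1L], rc[2L], lo, hi))
  }
  g <- floor((x - lo) / (hi - lo) * n_bins)
  g[!is.na(g) & g == n_bins] <- n_bins - 1  # close the top bin
  storage.mode(g) <- "integer"
  gsc_raster(g, missing_code = missing_code)
}
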