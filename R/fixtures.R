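#' Synthetic gray-level rasters
#'
#' Reproducible generator of structured test maps. The same recipe and seed
#' always produce the same raster.
#'
#' Kinds:
#' * `constant` -- every cell equal to `value`.
#' * `checkerboard` -- strict alternation of the first two `levels`.
#' * `gradient` -- levels sweeping linearly across columns from
#'   `min(levels)` to `max(levels)`.
#' * `random` -- i.i.d. uniform draws from `levels` (categorical map).
#' * `binned` -- smooth random numeric surface (sums of sinusoids)
#'   quantized onto `levels` via [gsc_quantize()].
#' * `blocks` -- random rectangular constant patches of `levels`.
#'
#' `missing_frac` then blanks a random fraction of cells in any kind.
#'
#' @param kind one of the kinds above
#' @param nrow,ncol raster dimensions
#' @param levels gray levels to use (default `0:100` for numeric kinds,
#'   `c(0, 50, 100)` for categorical ones)
#' @param value constant value for `kind = "constant"`
#' @param missing_frac fraction of cells set missing, in `[0, 1]`
#' @param seed integer seed driving all randomness in the recipe
#' @return a [gsc_raster()]
#' @examples
#' gsc_fixture("checkerboard", 8, 8, levels = c(10, 90))
#' gsc_fixture("random", 20, 20, levels = 0:10, missing_frac = 0.1, seed = 7)
#' @export
gsc_fixture <- function(kind = c("constant", "checkerboard", "gradient",
                                 "random", "binned", "blocks"),
                        nrow = 16L, ncol = 16L, levels = NULL, value = 50L,
                        missing_frac = 0, seed = 1L) {
  kind <- match.arg(kind)
  if (missing_frac < 0 || missing_frac > 1)
    stop("`missing_frac` must be in [0, 1]")
  if (is.null(levels))
    levels <- if (kind %in% c("gradient", "binned")) 0:100 else c(0L, 50L, 100L)
  levels <- as.integer(levels)
  if (any(levels < 0L | levels > 100L)) stop("levels must lie in [0, 100]")
  nrow <- as.integer(nrow); ncol <- as.integer(ncol)
  set.seed(as.integer(seed))
  v <- switch(kind,
    constant = matrix(as.integer(value), nrow, ncol),
    checkerboard = {
      a <- levels[1L]; b <- levels[2L]
      outer(seq_len(nrow), seq_len(ncol),
            function(r, c) ifelse((r + c) %% 2L == 0L, a, b))
    },
    gradient = {
      lo <- min(levels); hi <- max(levels)
      g <- if (ncol == 1L) matrix(lo, nrow, 1L)
           else matrix(rep(round(seq(lo, hi, length.out = ncol)), each = nrow),
                       nrow, ncol)
      g
    },
    random = matrix(sample(levels, nrow * ncol, replace = TRUE), nrow, ncol),
    binned = {
      r <- matrix(rep(seq_len(nrow), ncol), nrow, ncol)
      cl <- matrix(rep(seq_len(ncol), each = nrow), nrow, ncol)
      ph <- stats::runif(4, 0, 2 * pi); fr <- stats::runif(4, 0.05, 0.3)
      z <- sin(fr[1] * r + ph[1]) + sin(fr[2] * cl + ph[2]) +
           0.5 * sin(fr[3] * (r + cl) + ph[3]) + 0.5 * sin(fr[4] * (r - cl) + ph[4])
      q <- gsc_quantize(z, range(z) + c(-1e-9, 1e-9), n_bins = length(unique(levels)))
      # map bin indices onto the requested level set
      lv <- sort(unique(levels))
      matrix(lv[q$values + 1L], nrow, ncol)
    },
    blocks = {
      g <- matrix(sample(levels, 1L), nrow, ncol)
      for (b in seq_len(max(3L, (nrow * ncol) %/% 40L))) {
        r0 <- sample(nrow, 1L); c0 <- sample(ncol, 1L)
        h <- sample(seq_len(max(1L, nrow %/% 3L)), 1L)
        w <- sample(seq_len(max(1L, ncol %/% 3L)), 1L)
        g[r0:min(nrow, r0 + h), c0:min(ncol, c0 + w)] <- sample(levels, 1L)
      }
      g
    })
  storage.mode(v) <- "integer"
  if (missing_frac > 0) {
    n_miss <- round(missing_frac * length(v))
    v[sample(length(v), n_miss)] <- NA_integer_
  }
  gsc_raster(v)
}
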