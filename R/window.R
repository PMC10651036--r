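# Moving-window traversal, global analysis and the multi-scale scalogram.
#
# The engine slides a square window one pixel at a time and maintains the
# dense frequency / adjacency count structures incrementally: entering
# columns of the window add their pixel and pair counts, leaving columns
# subtract theirs. Derived statistics are recomputed per window from the
# integer counts, so there is no floating-point drift and the result is
# identical to rebuilding every window from scratch (the `engine`
# argument exposes the scratch rebuild for verification). Windows
# overhanging the map edge shrink to the in-bounds pixels, so the output
# keeps the full input extent.

#' Moving-window metric map
#'
#' Evaluates a metric on the square window centered at every pixel and
#' writes the value at that pixel, producing a continuous metric map at
#' the input resolution. Windows with no countable pixels (or pairs) give
#' nodata (`NA`).
#'
#' @param raster a [gsc_raster()]
#' @param metric metric id or short name ([gsc_metrics()])
#' @param window odd window side length >= 3
#' @param exclude_zero treat gray level 0 as missing in all tabulations?
#' @param t1,t2,kstar target parameters, where the metric requires them
#' @param engine `"incremental"` (default) or `"rebuild"` (per-window
#'   scratch tabulation; same output, used for verification)
#' @return object of class `gsc_map`: list with `values` (numeric matrix,
#'   `NA` = nodata) and metadata (`metric`, `short_name`, `window`,
#'   `exclude_zero`, `params`).
#' @examples
#' r <- gsc_fixture("random", 20, 20, levels = 0:8, seed = 3)
#' m <- gsc_moving_window(r, "GSDiversity", window = 5)
#' summary(m)
#' @export
gsc_moving_window <- function(raster, metric, window, exclude_zero = FALSE,
                              t1 = NULL, t2 = NULL, kstar = NULL,
                              engine = c("incremental", "rebuild")) {
  stopifnot(inherits(raster, "gsc_raster"))
  engine <- match.arg(engine)
  spec <- gsc_metric_spec(metric)
  gsc_check_params(spec, t1, t2, kstar)
  window <- as.integer(window)
  if (window < 3L || window %% 2L == 0L)
    stop("`window` must be an odd integer >= 3 (the center pixel must exist)")
  v <- raster$values
  if (exclude_zero) v[!is.na(v) & v == 0L] <- NA_integer_
  gr <- if (spec$id == 35L) {
    ok <- !is.na(v)
    if (any(ok)) diff(range(v[ok])) else NA_integer_
  } else NULL
  R <- nrow(v); C <- ncol(v); h <- (window - 1L) %/% 2L
  out <- matrix(NA_real_, R, C)
  need_f <- spec$needs_freq; need_a <- spec$needs_adj

  if (engine == "rebuild") {
    rr <- gsc_raster(v, missing_code = raster$missing_code)
    for (r in seq_len(R)) for (cc in seq_len(C)) {
      rows <- max(1L, r - h):min(R, r + h)
      cols <- max(1L, cc - h):min(C, cc + h)
      f <- if (need_f) gsc_tab_frequency(rr, rows, cols) else NULL
      a <- if (need_a) gsc_tab_adjacency(rr, rows, cols) else NULL
      out[r, cc] <- gsc_evaluate(spec$id, freq = f, adj = a, t1 = t1, t2 = t2,
                                 kstar = kstar, global_range = gr)
    }
  } else {
    fcounts <- numeric(101L)
    acounts <- matrix(0, 101L, 101L)
    r0 <- r1 <- 0L
    add_pairs <- function(a, b, sgn) {
      ok <- !is.na(a) & !is.na(b)
      if (any(ok)) {
        idx <- b[ok] * 101L + a[ok] + 1L
        acounts <<- acounts + sgn * matrix(tabulate(idx, 101L * 101L), 101L, 101L)
      }
    }
    upd_col <- function(ci, sgn) {
      col <- v[r0:r1, ci]
      ok <- !is.na(col)
      if (need_f && any(ok))
        fcounts <<- fcounts + sgn * tabulate(col[ok] + 1L, 101L)
      if (need_a) {
        n <- length(col)
        if (n > 1L) add_pairs(col[-n], col[-1L], sgn)   # vertical pairs
      }
    }
    link_cols <- function(cl, cr, sgn)                  # horizontal pairs cl-cr
      add_pairs(v[r0:r1, cl], v[r0:r1, cr], sgn)
    for (r in seq_len(R)) {
      r0 <- max(1L, r - h); r1 <- min(R, r + h)
      fcounts[] <- 0; acounts[] <- 0
      c0 <- 1L; c1 <- min(C, 1L + h)
      for (ci in c0:c1) {
        upd_col(ci, 1)
        if (need_a && ci > c0) link_cols(ci - 1L, ci, 1)
      }
      for (cc in seq_len(C)) {
        if (cc > 1L) {
          n0 <- max(1L, cc - h); n1 <- min(C, cc + h)
          if (n0 > c0) for (ci in c0:(n0 - 1L)) {       # columns leaving left
            upd_col(ci, -1)
            if (need_a) link_cols(ci, ci + 1L, -1)
          }
          if (n1 > c1) for (ci in (c1 + 1L):n1) {       # columns entering right
            upd_col(ci, 1)
            if (need_a) link_cols(ci - 1L, ci, 1)
          }
          c0 <- n0; c1 <- n1
        }
        f <- if (need_f) structure(list(counts = fcounts, total = sum(fcounts)),
                                   class = "gsc_freq") else NULL
        a <- if (need_a) structure(list(counts = acounts, total = sum(acounts)),
                                   class = "gsc_adj") else NULL
        out[r, cc] <- gsc_evaluate(spec$id, freq = f, adj = a, t1 = t1, t2 = t2,
                                   kstar = kstar, global_range = gr)
      }
    }
  }
  structure(list(values = out, metric = spec$id, short_name = spec$short_name,
                 window = window, exclude_zero = exclude_zero,
                 params = list(t1 = t1, t2 = t2, kstar = kstar)),
            class = "gsc_map")
}

#' Global (whole-extent) metric value
#'
#' Computes a single metric value from the tabulation of the entire map.
#' Equals the moving-window output at any pixel whose window covers the
#' whole map.
#'
#' @inheritParams gsc_moving_window
#' @return object of class `gsc_global`: list with `value` (`NA` when a
#'   guard fails or no valid data), `metric`, `short_name`, `exclude_zero`
#'   and `params`. Render with `print()` or [gsc_global_report()].
#' @examples
#' r <- gsc_fixture("constant", 6, 6, value = 40)
#' gsc_global(r, "Mean")$value    # 40
#' @export
gsc_global <- function(raster, metric, exclude_zero = FALSE,
                       t1 = NULL, t2 = NULL, kstar = NULL) {
  stopifnot(inherits(raster, "gsc_raster"))
  spec <- gsc_metric_spec(metric)
  gsc_check_params(spec, t1, t2, kstar)
  f <- if (spec$needs_freq)
    gsc_tab_frequency(raster, exclude_zero = exclude_zero) else NULL
  a <- if (spec$needs_adj)
    gsc_tab_adjacency(raster, exclude_zero = exclude_zero) else NULL
  gr <- if (spec$id == 35L) {
    s <- gsc_tab_frequency(raster, exclude_zero = exclude_zero)
    st <- if (s$total > 0) gsc_freq_stats(s) else NULL
    if (is.null(st)) NA_integer_ else st$max_level - st$min_level
  } else NULL
  val <- gsc_evaluate(spec$id, freq = f, adj = a, t1 = t1, t2 = t2,
                      kstar = kstar, global_range = gr)
  structure(list(value = val, metric = spec$id, short_name = spec$short_name,
                 exclude_zero = exclude_zero,
                 params = list(t1 = t1, t2 = t2, kstar = kstar)),
            class = "gsc_global")
}

#' Text report for a global analysis
#'
#' @param x a `gsc_global` result
#' @return character vector of report lines (metric id, name, parameters,
#'   value); the format written by the CLI in global mode.
#' @export
gsc_global_report <- function(x) {
  stopifnot(inherits(x, "gsc_global"))
  ps <- x$params[!vapply(x$params, is.null, TRUE)]
  c(sprintf("metric: %d", x$metric),
    sprintf("name: %s", x$short_name),
    sprintf("exclude_zero: %s", tolower(as.character(x$exclude_zero))),
    if (length(ps)) sprintf("%s: %d", names(ps), unlist(ps)) else "parameters: none",
    sprintf("value: %s",
            if (is.na(x$value)) "missing" else format(x$value, digits = 15)))
}

#' @export
print.gsc_global <- function(x, ...) {
  writeLines(gsc_global_report(x))
  invisible(x)
}

#' Multi-scale scalogram
#'
#' Runs the moving-window analysis over a series of window sizes and
#' reduces each metric map to one summary value, giving a curve of pattern
#' versus observation scale. The default grid is 21 window sizes, 5x5
#' through 45x45 in steps of 2, summarized by the maximum over all
#' windows; a plateau in the curve suggests a scale domain.
#'
#' @inheritParams gsc_moving_window
#' @param sides odd window side lengths (default `seq(5, 45, by = 2)`)
#' @param summary reduction over non-nodata pixels of each map: `"max"`,
#'   `"mean"` or `"quantile"`
#' @param prob probability for `summary = "quantile"`
#' @return object of class `gsc_scalogram`: data.frame with columns `side`
#'   and `value`, with the metric and summary recorded as attributes.
#' @export
gsc_scalogram <- function(raster, metric, sides = seq(5L, 45L, by = 2L),
                          summary = c("max", "mean", "quantile"), prob = 0.95,
                          exclude_zero = FALSE,
                          t1 = NULL, t2 = NULL, kstar = NULL) {
  summary <- match.arg(summary)
  if (length(sides) == 0L) stop("`sides` must name at least one window size")
  red <- switch(summary,
                max = function(z) if (all(is.na(z))) NA_real_ else max(z, na.rm = TRUE),
                mean = function(z) if (all(is.na(z))) NA_real_ else mean(z, na.rm = TRUE),
                quantile = function(z) if (all(is.na(z))) NA_real_ else
                  stats::quantile(z, prob, na.rm = TRUE, names = FALSE))
  vals <- vapply(sides, function(s) {
    m <- gsc_moving_window(raster, metric, window = s,
                           exclude_zero = exclude_zero,
                           t1 = t1, t2 = t2, kstar = kstar)
    red(m$values)
  }, numeric(1L))
  out <- data.frame(side = as.integer(sides), value = vals)
  attr(out, "metric") <- gsc_metric_spec(metric)$id
  attr(out, "summary") <- summary
  class(out) <- c("gsc_scalogram", "data.frame")
  out
}

#' @export
plot.gsc_scalogram <- function(x, ...) {
  graphics::plot(x$side, x$value, type = "b", pch = 16,
                 xlab = "window side length (pixels)",
                 ylab = sprintf("%s metric value", attr(x, "summary")), ...)
  invisible(x)
}

#' Ground area covered by a square window
#'
#' Converts a window side length and pixel resolution to the window's
#' ground area, the quantity usually quoted when reporting the observation
#' scale of a moving-window analysis (e.g. at 2430 m resolution a 31x31
#' window covers about 5675 km^2).
#'
#' @param side window side length in pixels
#' @param resolution pixel edge length in meters
#' @return area in square kilometers
#' @examples
#' gsc_window_area(31, 2430)
#' @export
gsc_window_area <- function(side, resolution) {
  (side * resolution / 1000)^2
}
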