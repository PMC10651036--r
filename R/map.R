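# Metric map class: the raster of metric values produced by the
# moving-window engine, aligned cell-for-cell with the input.

#' @export
as.matrix.gsc_map <- function(x, ...) x$values

#' @export
dim.gsc_map <- function(x) dim(x$values)

#' @export
print.gsc_map <- function(x, ...) {
  v <- x$values
  cat(sprintf("<gsc_map> metric %d (%s), window %dx%d\n",
              x$metric, x$short_name, x$window, x$window))
  cat(sprintf("  %d x %d cells, %d nodata\n", nrow(v), ncol(v), sum(is.na(v))))
  if (any(!is.na(v)))
    cat(sprintf("  value range: [%g, %g]\n", min(v, na.rm = TRUE),
                max(v, na.rm = TRUE)))
  invisible(x)
}

#' @export
summary.gsc_map <- function(object, ...) {
  v <- object$values
  cat(sprintf("Metric map: %d (%s), window %dx%d, exclude_zero = %s\n",
              object$metric, object$short_name, object$window, object$window,
              object$exclude_zero))
  cat(sprintf("  cells: %d, nodata: %d\n", length(v), sum(is.na(v))))
  print(summary(as.vector(v)))
  invisible(object)
}

#' @export
plot.gsc_map <- function(x, ..., col = grDevices::gray.colors(64, rev = TRUE)) {
  v <- x$values
  # image() draws x right/y up; transpose and flip rows to draw map-style
  graphics::image(t(v[nrow(v):1, , drop = FALSE]), col = col, axes = FALSE,
                  main = sprintf("metric %d (%s), window %d", x$metric,
                                 x$short_name, x$window), ...)
  invisible(x)
}
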