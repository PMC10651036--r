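# Raster input/output.
#
# Dialects:
# * 8-bit single-band TIFF (.tif/.tiff) for gray-level input and byte
#   metric output, via the `tiff` package. Missing data use the byte code
#   255. Georeferencing tags are not carried (no GDAL binding is used);
#   pair outputs with the original world file if needed.
# * Headerless flat binary (.raw/.bin), 8-bit unsigned, row-major, with
#   explicit dimensions, for minimal workflows.
# * 32-bit float single-band TIFF for float metric output. `tiff::writeTIFF`
#   stores float samples only on [0, 1], so the writer here emits a minimal
#   uncompressed baseline TIFF (SampleFormat = IEEE float, one strip)
#   directly; nodata is NaN. `tiff::readTIFF` reads these files back.

#' Read a gray-level raster
#'
#' Accepts single-band 8-bit TIFF, or headerless flat binary 8-bit with
#' explicit dimensions. Values must be integers in \[0, 100\] or the
#' missing code; anything else is an error (numeric rasters must be
#' quantized first, see [gsc_quantize()]).
#'
#' @param path file to read
#' @param nrow,ncol dimensions, required for flat binary input (row-major
#'   pixel order)
#' @param missing_code byte value marking missing pixels (default 255)
#' @return a [gsc_raster()]
#' @export
gsc_read_raster <- function(path, nrow = NULL, ncol = NULL, missing_code = 255L) {
  if (!file.exists(path)) stop(sprintf("input file not found: %s", path))
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    img <- tryCatch(tiff::readTIFF(path, as.is = TRUE), error = function(e) {
      if (grepl("floating point", conditionMessage(e)))
        stop("float-typed raster: quantize numeric data into gray levels first (gsc_quantize)",
             call. = FALSE)
      stop(e)
    })
    if (length(dim(img)) == 3L) {
      if (dim(img)[3L] == 1L) img <- img[, , 1L]
      else stop("multi-band TIFF: supply a single-band gray-level raster")
    }
    if (any(abs(img - round(img)) > 1e-9, na.rm = TRUE))
      stop("float-typed raster: quantize numeric data into gray levels first (gsc_quantize)")
    v <- img
    storage.mode(v) <- "integer"
  } else {
    if (is.null(nrow) || is.null(ncol))
      stop("flat binary input needs explicit `nrow` and `ncol`")
    raw <- readBin(path, what = "integer", n = nrow * ncol, size = 1L,
                   signed = FALSE)
    if (length(raw) != nrow * ncol)
      stop(sprintf("expected %d bytes, file holds %d", nrow * ncol, length(raw)))
    v <- matrix(raw, nrow = nrow, ncol = ncol, byrow = TRUE)
  }
  bad <- !is.na(v) & v != missing_code & (v < 0L | v > 100L)
  if (any(bad))
    stop(sprintf("%d pixel(s) outside [0, 100] and not the missing code %d",
                 sum(bad), missing_code))
  gsc_raster(v, missing_code = missing_code)
}

#' Write a gray-level raster
#'
#' 8-bit TIFF (.tif/.tiff) or headerless flat binary (row-major) by file
#' extension; missing cells are written as the raster's missing code.
#'
#' @param raster a [gsc_raster()]
#' @param path output file
#' @return the path, invisibly
#' @export
gsc_write_raster <- function(raster, path) {
  stopifnot(inherits(raster, "gsc_raster"))
  v <- raster$values
  v[is.na(v)] <- raster$missing_code
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    tiff::writeTIFF(v / 255, path, bits.per.sample = 8L)
  } else {
    writeBin(as.integer(t(v)), path, size = 1L)
  }
  invisible(path)
}

# Minimal uncompressed baseline TIFF, one strip, 32-bit IEEE float
# samples, little-endian. Enough tags for standard readers.
gsc_write_float_tiff <- function(values, path) {
  w <- ncol(values); h <- nrow(values)
  con <- file(path, "wb")
  on.exit(close(con))
  data_off <- 8L
  data_len <- 4L * w * h
  ifd_off <- data_off + data_len
  writeBin(charToRaw("II"), con)
  writeBin(42L, con, size = 2L, endian = "little")
  writeBin(as.integer(ifd_off), con, size = 4L, endian = "little")
  writeBin(as.vector(t(values)), con, size = 4L, endian = "little")  # row-major strip
  tag <- function(id, type, count, value) {
    writeBin(as.integer(id), con, size = 2L, endian = "little")
    writeBin(as.integer(type), con, size = 2L, endian = "little")
    writeBin(as.integer(count), con, size = 4L, endian = "little")
    if (type == 3L) {  # SHORT, left-justified in the 4-byte slot
      writeBin(as.integer(value), con, size = 2L, endian = "little")
      writeBin(0L, con, size = 2L, endian = "little")
    } else {
      writeBin(as.integer(value), con, size = 4L, endian = "little")
    }
  }
  entries <- list(
    list(256L, 4L, 1L, w),          # ImageWidth
    list(257L, 4L, 1L, h),          # ImageLength
    list(258L, 3L, 1L, 32L),        # BitsPerSample
    list(259L, 3L, 1L, 1L),         # Compression: none
    list(262L, 3L, 1L, 1L),         # Photometric: BlackIsZero
    list(273L, 4L, 1L, data_off),   # StripOffsets
    list(277L, 3L, 1L, 1L),         # SamplesPerPixel
    list(278L, 4L, 1L, h),          # RowsPerStrip
    list(279L, 4L, 1L, data_len),   # StripByteCounts
    list(339L, 3L, 1L, 3L)          # SampleFormat: IEEE float
  )
  writeBin(as.integer(length(entries)), con, size = 2L, endian = "little")
  for (e in entries) do.call(tag, e)
  writeBin(0L, con, size = 4L, endian = "little")  # no next IFD
  invisible(path)
}

#' Write a metric map
#'
#' Float mode writes a 32-bit float single-band TIFF (nodata = NaN) or,
#' for non-TIFF extensions, raw float32 (row-major). Byte mode writes an
#' 8-bit TIFF (or raw bytes) under the byte-scaling rule: metrics bounded
#' on \[0, 1\] are stored as `round(100 * value)`; integer-valued and
#' \[0, 100\]-bounded metrics (and mosaic class codes) are stored as
#' `round(value)`; nodata is 255. Metrics whose values do not fit that
#' scheme (unbounded metrics, and Correlation with its \[-1, 1\] range)
#' refuse byte mode.
#'
#' Maps of the mosaic metrics also get a `<path>_legend.txt` class legend.
#'
#' @param map a `gsc_map` from [gsc_moving_window()]
#' @param path output file (.tif/.tiff, or raw binary otherwise)
#' @param precision `"float"` (default) or `"byte"`
#' @return the path, invisibly
#' @export
gsc_write_map <- function(map, path, precision = c("float", "byte")) {
  stopifnot(inherits(map, "gsc_map"))
  precision <- match.arg(precision)
  spec <- gsc_metric_spec(map$metric)
  is_tif <- grepl("\\.tiff?$", path, ignore.case = TRUE)
  if (precision == "float") {
    v <- map$values
    v[is.na(v)] <- NaN
    if (is_tif) gsc_write_float_tiff(v, path)
    else writeBin(as.vector(t(v)), path, size = 4L, endian = "little")
  } else {
    if (!spec$byte_ok) {
      ok <- gsc_metrics()
      stop(sprintf(paste0("metric %d (%s) cannot be written in byte mode; ",
                          "byte-eligible metrics: %s"),
                   spec$id, spec$short_name,
                   paste(ok$id[ok$byte_ok], collapse = ", ")))
    }
    scale <- if (!spec$integer_out && spec$upper <= 1) 100 else 1
    b <- round(map$values * scale)
    b[is.na(b)] <- 255
    if (is_tif) tiff::writeTIFF(b / 255, path, bits.per.sample = 8L)
    else writeBin(as.integer(t(b)), path, size = 1L)
  }
  if (spec$id %in% c(17L, 18L))
    gsc_write_mosaic_legend(paste0(path, "_legend.txt"),
                            if (spec$id == 17L) 19L else 103L)
  invisible(path)
}

#' Read a float32 metric map written by [gsc_write_map()]
#'
#' @param path TIFF file (float samples); NaN cells come back as `NA`
#' @return numeric matrix
#' @export
gsc_read_map <- function(path) {
  v <- tiff::readTIFF(path)
  if (length(dim(v)) == 3L) v <- v[, , 1L]
  v[is.nan(v)] <- NA_real_
  v
}
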