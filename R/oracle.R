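# Independent brute-force oracle.
#
# Evaluates every metric by literal transcription of its definition over
# an explicitly enumerated pixel list and neighbor-pair list, with nested
# loops over gray levels and no code shared with the dense-array engine or
# the incremental window machinery. Deliberately slow; intended for
# verification on small regions.

#' Brute-force oracle evaluation of a metric
#'
#' Reference implementation used to verify the engine: enumerates the
#' pixels and the below/right neighbor pairs of a (small) region and
#' computes the metric definition by direct summation.
#'
#' @inheritParams gsc_tab_frequency
#' @param metric metric id or short name
#' @param t1,t2,kstar target parameters where required
#' @param global_range gray-level range of the whole map (metric 35); by
#'   default computed from the full raster under the same zero policy
#' @return single numeric value with the same missing-value semantics as
#'   [gsc_evaluate()].
#' @export
gsc_oracle <- function(raster, metric, rows = NULL, cols = NULL,
                       exclude_zero = FALSE, t1 = NULL, t2 = NULL,
                       kstar = NULL, global_range = NULL) {
  stopifnot(inherits(raster, "gsc_raster"))
  spec <- gsc_metric_spec(metric)
  gsc_check_params(spec, t1, t2, kstar)
  id <- spec$id
  m <- raster$values
  if (is.null(rows)) rows <- seq_len(nrow(m))
  if (is.null(cols)) cols <- seq_len(ncol(m))
  valid <- function(z) !is.na(z) && !(exclude_zero && z == 0L)

  vals <- integer(0)
  for (r in rows) for (cc in cols)
    if (valid(m[r, cc])) vals <- c(vals, m[r, cc])

  pa <- integer(0); pb <- integer(0)  # upper/left member, lower/right member
  for (r in rows) for (cc in cols) {
    if ((r + 1L) %in% rows && valid(m[r, cc]) && valid(m[r + 1L, cc])) {
      pa <- c(pa, m[r, cc]); pb <- c(pb, m[r + 1L, cc])
    }
    if ((cc + 1L) %in% cols && valid(m[r, cc]) && valid(m[r, cc + 1L])) {
      pa <- c(pa, m[r, cc]); pb <- c(pb, m[r, cc + 1L])
    }
  }

  if (spec$needs_freq) {
    n <- length(vals)
    if (n == 0L) return(NA_real_)
    lv <- sort(unique(vals))
    p <- vapply(lv, function(l) sum(vals == l) / n, numeric(1))
    mu <- 0; for (q in seq_along(lv)) mu <- mu + lv[q] * p[q]
    s2 <- 0; for (q in seq_along(lv)) s2 <- s2 + (lv[q] - mu)^2 * p[q]
    Ng <- length(lv)
  }
  if (spec$needs_adj) {
    np <- length(pa)
    if (np == 0L) return(NA_real_)
    lvp <- sort(unique(c(pa, pb)))
    pc <- function(i, j) sum(pa == i & pb == j) / np
    NgA <- length(lvp)
    if (id == 35L && is.null(global_range)) {
      allv <- m[!is.na(m)]
      if (exclude_zero) allv <- allv[allv != 0L]
      global_range <- if (length(allv)) max(allv) - min(allv) else NA_integer_
    }
  }
  H <- function(ps) { s <- 0; for (z in ps) if (z > 0) s <- s - z * log(z); s }

  switch(as.character(id),
    "1" = mu,
    "2" = {
      if (NgA <= 1) return(NA_real_)
      s <- 0
      for (i in lvp) for (j in lvp) { z <- pc(i, j); if (z > 0) s <- s - z * log(z) }
      s / (2 * log(NgA))
    },
    "3" = {
      if (NgA <= 1) return(NA_real_)
      s <- 0
      for (i in lvp) for (j in lvp[lvp >= i]) {
        z <- if (i == j) pc(i, i) else pc(i, j) + pc(j, i)
        if (z > 0) s <- s - z * log(z)
      }
      s / (log(NgA^2 + NgA) - log(2))
    },
    "4" = {
      s <- 0
      for (i in lvp) for (j in lvp) { z <- pc(i, j); if (z > 0) s <- s - z * log(z) }
      s
    },
    "5" = {
      s <- 0
      for (i in lvp) for (j in lvp[lvp >= i]) {
        z <- if (i == j) pc(i, i) else pc(i, j) + pc(j, i)
        if (z > 0) s <- s - z * log(z)
      }
      s
    },
    "6" = { s <- 0; for (i in lvp) s <- s + pc(i, i); s },
    "7" = H(p),
    "8" = if (Ng > 1) H(p) / log(Ng) else NA_real_,
    "9" = sort(vals)[floor((length(vals) + 1) / 2)],
    "10" = { s <- 0; for (q in seq_along(lv)) s <- s + p[q]^2; 1 - s },
    "11" = {
      if (Ng <= 1) return(NA_real_)
      s <- 0; for (q in seq_along(lv)) s <- s + p[q]^2
      (1 - s) / (1 - 1 / Ng)
    },
    "12" = {
      if (NgA <= 1) return(NA_real_)
      s <- 0; for (i in lvp) for (j in lvp) s <- s + pc(i, j)^2
      (1 - s) / (1 - 1 / NgA^2)
    },
    "13" = {
      if (NgA <= 1) return(NA_real_)
      s <- 0
      for (i in lvp) for (j in lvp[lvp >= i])
        s <- s + (if (i == j) pc(i, i) else pc(i, j) + pc(j, i))^2
      (1 - s) / (1 - 2 / (NgA^2 + NgA))
    },
    "14" = { s <- 0; for (i in lvp) for (j in lvp) s <- s + pc(i, j)^2; 1 - s },
    "15" = {
      s <- 0
      for (i in lvp) for (j in lvp[lvp >= i])
        s <- s + (if (i == j) pc(i, i) else pc(i, j) + pc(j, i))^2
      1 - s
    },
    "16" = lv[which(p == max(p))[1L]],
    "17" = gsc_oracle_mosaic(vals, 19L),
    "18" = gsc_oracle_mosaic(vals, 103L),
    "19" = Ng,
    "20" = max(p),
    "21" = { q <- which(lv == t1); if (length(q)) p[q] else 0 },
    "22" = sum(pa == t1 | pb == t1) / np,
    "23" = if (t1 != t2) (sum(pa == t1 & pb == t2) + sum(pa == t2 & pb == t1)) / np
           else sum(pa == t1 & pb == t1) / np,
    "24" = {
      denom <- sum(pa == t1 | pb == t1)
      if (denom == 0L) return(NA_real_)
      if (t1 != t2) (sum(pa == t1 & pb == t2) + sum(pa == t2 & pb == t1)) / denom
      else sum(pa == t1 & pb == t1) / denom
    },
    "25" = sqrt(s2),
    "26" = if (mu > 0) 100 * sqrt(s2) / mu else NA_real_,
    "27" = max(vals) - min(vals),
    "28" = { s <- 0; for (i in lvp) for (j in lvp) s <- s + abs(i - j) * pc(i, j); s },
    "29" = { s <- 0; for (i in lvp) for (j in lvp) s <- s + (i - j)^2 * pc(i, j); s },
    "30" = { s <- 0; for (i in lvp) for (j in lvp) s <- s + pc(i, j)^2; s },
    "31" = {
      s <- 0
      for (i in lvp) for (j in lvp[lvp >= i])
        s <- s + (if (i == j) pc(i, i) else pc(i, j) + pc(j, i))^2
      s
    },
    "32" = { s <- 0; for (i in lvp) for (j in lvp) s <- s + pc(i, j) / (1 + (i - j)^2); s },
    "33" = { s <- 0; for (i in lvp) for (j in lvp) s <- s + pc(i, j) / (1 + abs(i - j)); s },
    "34" = {
      s <- 0; for (i in lvp) for (j in lvp) s <- s + abs(i - j) * pc(i, j)
      1 - s / 100
    },
    "35" = {
      if (is.na(global_range) || global_range <= 0) return(NA_real_)
      s <- 0; for (i in lvp) for (j in lvp) s <- s + abs(i - j) * pc(i, j)
      1 - s / global_range
    },
    "36" = {
      wr <- max(lvp) - min(lvp)
      if (wr <= 0) return(NA_real_)
      s <- 0; for (i in lvp) for (j in lvp) s <- s + abs(i - j) * pc(i, j)
      1 - s / wr
    },
    "37" = { b <- 0; for (i in lvp) for (j in lvp) b <- max(b, pc(i, j)); b },
    "38" = {
      b <- 0
      for (i in lvp) for (j in lvp[lvp >= i])
        b <- max(b, if (i == j) pc(i, i) else pc(i, j) + pc(j, i))
      b
    },
    "39" = H(vapply(0:100, function(k) sum(abs(pa - pb) == k) / np, numeric(1))),
    "40" = {
      pk <- vapply(0:100, function(k) sum(abs(pa - pb) == k) / np, numeric(1))
      nk <- sum(pk > 0)
      if (nk > 1) H(pk) / log(nk) else NA_real_
    },
    "41" = H(vapply(0:200, function(k) sum(pa + pb == k) / np, numeric(1))),
    "42" = {
      pk <- vapply(0:200, function(k) sum(pa + pb == k) / np, numeric(1))
      nk <- sum(pk > 0)
      if (nk > 1) H(pk) / log(nk) else NA_real_
    },
    "43" = { s <- 0; for (i in lvp) for (j in lvp) s <- s + i * j * pc(i, j); s },
    "44" = {
      mux <- 0; muy <- 0
      for (i in lvp) mux <- mux + i * sum(pa == i) / np
      for (j in lvp) muy <- muy + j * sum(pb == j) / np
      sx2 <- 0; sy2 <- 0
      for (i in lvp) sx2 <- sx2 + (i - mux)^2 * sum(pa == i) / np
      for (j in lvp) sy2 <- sy2 + (j - muy)^2 * sum(pb == j) / np
      if (sx2 <= 0 || sy2 <= 0) return(NA_real_)
      s <- 0
      for (i in lvp) for (j in lvp)
        s <- s + ((i - mux) / sqrt(sx2)) * ((j - muy) / sqrt(sy2)) * pc(i, j)
      s
    },
    "45" = {
      mux <- sum(pa) / np; muy <- sum(pb) / np
      s <- 0
      for (i in lvp) for (j in lvp) s <- s + (i + j - mux - muy)^3 * pc(i, j)
      s
    },
    "46" = {
      mux <- sum(pa) / np; muy <- sum(pb) / np
      s <- 0
      for (i in lvp) for (j in lvp) s <- s + (i + j - mux - muy)^4 * pc(i, j)
      s
    },
    "47" = { s <- 0; for (q in seq_along(lv)) s <- s + lv[q]^2 * p[q]; sqrt(s) },
    "48" = { s <- 0; for (q in seq_along(lv)) s <- s + abs(lv[q] - mu) * p[q]; s },
    "49" = sum(abs(pa - pb) <= kstar) / np,
    "50" = {
      if (s2 <= 0) return(NA_real_)
      s <- 0; for (q in seq_along(lv)) s <- s + (lv[q] - mu)^3 * p[q]
      s / sqrt(s2)^3
    },
    "51" = {
      if (s2 <= 0) return(NA_real_)
      s <- 0; for (q in seq_along(lv)) s <- s + (lv[q] - mu)^4 * p[q]
      s / s2^2
    },
    stop(sprintf("oracle: unknown metric id %d", id))
  )
}

# Mosaic classification for the oracle: recompute the composition by
# counting, then delegate to the published-partition classifier (the
# partition itself has its own enumeration tests).
gsc_oracle_mosaic <- function(vals, variant) {
  n <- length(vals)
  p1 <- sum(vals == 1L) / n; p2 <- sum(vals == 2L) / n; p3 <- sum(vals == 3L) / n
  gsc_classify_mosaic1(p1, p2, p3, variant)
}
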