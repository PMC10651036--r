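# Metric evaluation from tabulations.
#
# All entropies use the natural logarithm. Guard conditions defined with
# the metrics (Ng > 1 for evenness, sigma > 0 for skewness/kurtosis, ...)
# yield a missing value (NA), never an error; errors are reserved for
# caller mistakes (unknown id, absent target parameters).

#' Evaluate a pattern metric on tabulations
#'
#' Computes one of the 51 registry metrics from a frequency and/or
#' adjacency tabulation built under a single consistent zero policy.
#'
#' @param metric metric id (1..51) or short name, see [gsc_metrics()]
#' @param freq [gsc_tab_frequency()] result (required by first-order metrics)
#' @param adj [gsc_tab_adjacency()] result (required by second-order metrics)
#' @param t1,t2 target gray levels (metrics 21-24)
#' @param kstar target difference level (metric 49)
#' @param global_range gray-level range of the whole map (metric 35 only)
#' @return single numeric value; `NA` when a guard fails or the needed
#'   tabulation is empty.
#' @examples
#' r <- gsc_fixture("checkerboard", 8, 8, levels = c(10, 90))
#' f <- gsc_tab_frequency(r); a <- gsc_tab_adjacency(r)
#' gsc_evaluate(10, freq = f)        # Gini-Simpson diversity = 0.5
#' gsc_evaluate(29, adj = a)         # contrast = (10 - 90)^2
#' @export
gsc_evaluate <- function(metric, freq = NULL, adj = NULL,
                         t1 = NULL, t2 = NULL, kstar = NULL,
                         global_range = NULL) {
  spec <- gsc_metric_spec(metric)
  gsc_check_params(spec, t1, t2, kstar)
  id <- spec$id
  if (spec$needs_freq) {
    if (is.null(freq)) stop(sprintf("metric %d requires a frequency tabulation", id))
    if (freq$total <= 0) return(NA_real_)
    fs <- gsc_freq_stats(freq)
  }
  if (spec$needs_adj) {
    if (is.null(adj)) stop(sprintf("metric %d requires an adjacency tabulation", id))
    if (adj$total <= 0) return(NA_real_)
    if (id == 35L && is.null(global_range))
      stop("metric 35 (SimilarityRGlobal) requires `global_range`")
    ad <- gsc_adj_distributions(adj)
  }
  lev <- 0:100
  ent <- function(p) { p <- p[p > 0]; -sum(p * log(p)) }
  # bounded metrics are clamped to their declared interval to absorb
  # last-bit floating-point overshoot (e.g. an evenness of 1 + 2e-16)
  clamp <- function(v) {
    if (!is.na(v) && spec$bounded) min(max(v, spec$lower), spec$upper) else v
  }
  return(clamp(gsc_evaluate_raw(spec, id, freq, adj, t1, t2, kstar,
                                global_range,
                                if (spec$needs_freq) fs else NULL,
                                if (spec$needs_adj) ad else NULL, lev, ent)))
}

gsc_evaluate_raw <- function(spec, id, freq, adj, t1, t2, kstar,
                             global_range, fs, ad, lev, ent) {

  if (spec$needs_adj) {
    # restrict heavy double sums to the gray levels present in the matrix
    keep <- (ad$px + ad$py) > 0
    Ps <- ad$p[keep, keep, drop = FALSE]
    li <- lev[keep]
    I <- matrix(li, length(li), length(li)); J <- t(I)
    Ng <- ad$n_levels
  }

  switch(as.character(id),
    "1" = fs$mu,
    "2" = if (Ng > 1) ent(ad$p) / (2 * log(Ng)) else NA_real_,
    "3" = if (Ng > 1) ent(ad$p_unord) / (log(Ng^2 + Ng) - log(2)) else NA_real_,
    "4" = ent(ad$p),
    "5" = ent(ad$p_unord),
    "6" = sum(diag(ad$p)),
    "7" = ent(fs$p),
    "8" = if (fs$n_levels > 1) ent(fs$p) / log(fs$n_levels) else NA_real_,
    "9" = {  # lower-middle order statistic, integer output
      n <- freq$total
      target <- floor((n + 1) / 2)
      as.numeric(lev[which(cumsum(freq$counts) >= target)[1L]])
    },
    "10" = 1 - sum(fs$p^2),
    "11" = if (fs$n_levels > 1) (1 - sum(fs$p^2)) / (1 - 1 / fs$n_levels) else NA_real_,
    "12" = if (Ng > 1) (1 - sum(ad$p^2)) / (1 - 1 / Ng^2) else NA_real_,
    "13" = if (Ng > 1) (1 - sum(ad$p_unord^2)) / (1 - 2 / (Ng^2 + Ng)) else NA_real_,
    "14" = 1 - sum(ad$p^2),
    "15" = 1 - sum(ad$p_unord^2),
    "16" = as.numeric(lev[which.max(fs$p)]),  # smallest tied level
    "17" = gsc_classify_mosaic1(fs$p[2L], fs$p[3L], fs$p[4L], 19L),
    "18" = gsc_classify_mosaic1(fs$p[2L], fs$p[3L], fs$p[4L], 103L),
    "19" = as.numeric(fs$n_levels),
    "20" = max(fs$p),
    "21" = fs$p[t1 + 1L],
    "22" = {
      x <- adj$counts
      (sum(x[t1 + 1L, ]) + sum(x[, t1 + 1L]) - x[t1 + 1L, t1 + 1L]) / adj$total
    },
    "23" = {
      x <- adj$counts
      if (t1 != t2) (x[t1 + 1L, t2 + 1L] + x[t2 + 1L, t1 + 1L]) / adj$total
      else x[t1 + 1L, t1 + 1L] / adj$total
    },
    "24" = {
      x <- adj$counts
      denom <- sum(x[t1 + 1L, ]) + sum(x[, t1 + 1L]) - x[t1 + 1L, t1 + 1L]
      if (denom <= 0) return(NA_real_)
      if (t1 != t2) (x[t1 + 1L, t2 + 1L] + x[t2 + 1L, t1 + 1L]) / denom
      else x[t1 + 1L, t1 + 1L] / denom
    },
    "25" = sqrt(fs$var),
    "26" = if (fs$mu > 0) 100 * sqrt(fs$var) / fs$mu else NA_real_,
    "27" = as.numeric(fs$max_level - fs$min_level),
    "28" = sum(abs(I - J) * Ps),
    "29" = sum((I - J)^2 * Ps),
    "30" = sum(ad$p^2),
    "31" = sum(ad$p_unord^2),
    "32" = sum(Ps / (1 + (I - J)^2)),
    "33" = sum(Ps / (1 + abs(I - J))),
    "34" = 1 - sum(abs(I - J) * Ps) / 100,
    "35" = if (global_range > 0) 1 - sum(abs(I - J) * Ps) / global_range else NA_real_,
    "36" = if (ad$range > 0) 1 - sum(abs(I - J) * Ps) / ad$range else NA_real_,
    "37" = max(ad$p),
    "38" = max(ad$p_unord),
    "39" = ent(ad$p_diff),
    "40" = if (ad$nk_diff > 1) ent(ad$p_diff) / log(ad$nk_diff) else NA_real_,
    "41" = ent(ad$p_sum),
    "42" = if (ad$nk_sum > 1) ent(ad$p_sum) / log(ad$nk_sum) else NA_real_,
    "43" = sum(I * J * Ps),
    "44" = {
      if (ad$var_x > 0 && ad$var_y > 0)
        sum((I - ad$mu_x) * (J - ad$mu_y) * Ps) / sqrt(ad$var_x * ad$var_y)
      else NA_real_
    },
    "45" = sum((I + J - ad$mu_x - ad$mu_y)^3 * Ps),
    "46" = sum((I + J - ad$mu_x - ad$mu_y)^4 * Ps),
    "47" = sqrt(sum(lev^2 * fs$p)),
    "48" = sum(abs(lev - fs$mu) * fs$p),
    "49" = sum(ad$p_diff[seq_len(kstar + 1L)]),
    "50" = if (fs$var > 0) sum((lev - fs$mu)^3 * fs$p) / fs$var^1.5 else NA_real_,
    "51" = if (fs$var > 0) sum((lev - fs$mu)^4 * fs$p) / fs$var^2 else NA_real_,
    stop(sprintf("unknown metric id %d", id))
  )
}
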