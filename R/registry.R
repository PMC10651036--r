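# Metric registry: ids 1..51, short names, required tabulations, input-type
# applicability (A = all, N = nominal only, O = ordinal/quantized-numeric
# only), output bounds and required target parameters.
#
# Notes on the catalogue:
# * Metric 25 is the population standard deviation and metric 47 the root
#   mean square (both carry the square root; SD is bounded by [0, 100] and
#   the coefficient of variation is 100*SD/mu).
# * Metric 41 (SumEntropy) carries no published bound; it is treated as an
#   unbounded real.
# * Metric 51 (Kurtosis) is applicable to ordinal data only: a fourth
#   moment is meaningless for nominal levels.

gsc_registry_build <- function() {
  # id, short_name, input, needs_freq, needs_adj, lower, upper, integer_out, params
  rows <- list(
    list(1L,  "Mean",                    "O", TRUE,  FALSE, 0,   100, FALSE, ""),
    list(2L,  "EvennessOrderedAdj",      "A", FALSE, TRUE,  0,   1,   FALSE, ""),
    list(3L,  "EvennessUnorderedAdj",    "A", FALSE, TRUE,  0,   1,   FALSE, ""),
    list(4L,  "EntropyOrderedAdj",       "A", FALSE, TRUE,  NA,  NA,  FALSE, ""),
    list(5L,  "EntropyUnorderedAdj",     "A", FALSE, TRUE,  NA,  NA,  FALSE, ""),
    list(6L,  "DiagonalContagion",       "A", FALSE, TRUE,  0,   1,   FALSE, ""),
    list(7L,  "ShannonDiversity",        "A", TRUE,  FALSE, NA,  NA,  FALSE, ""),
    list(8L,  "ShannonEvenness",         "A", TRUE,  FALSE, 0,   1,   FALSE, ""),
    list(9L,  "Median",                  "O", TRUE,  FALSE, 0,   100, TRUE,  ""),
    list(10L, "GSDiversity",             "A", TRUE,  FALSE, 0,   1,   FALSE, ""),
    list(11L, "GSEvenness",              "A", TRUE,  FALSE, 0,   1,   FALSE, ""),
    list(12L, "EquitabilityOrderedAdj",  "A", FALSE, TRUE,  0,   1,   FALSE, ""),
    list(13L, "EquitabilityUnorderedAdj","A", FALSE, TRUE,  0,   1,   FALSE, ""),
    list(14L, "DiversityOrderedAdj",     "A", FALSE, TRUE,  0,   1,   FALSE, ""),
    list(15L, "DiversityUnorderedAdj",   "A", FALSE, TRUE,  0,   1,   FALSE, ""),
    list(16L, "Majority",                "A", TRUE,  FALSE, 0,   100, TRUE,  ""),
    list(17L, "LandscapeMosaic19",       "N", TRUE,  FALSE, 1,   19,  TRUE,  ""),
    list(18L, "LandscapeMosaic103",      "N", TRUE,  FALSE, 1,   103, TRUE,  ""),
    list(19L, "NumberGrayLevels",        "A", TRUE,  FALSE, 1,   100, TRUE,  ""),
    list(20L, "MaxAreaDensity",          "A", TRUE,  FALSE, 0,   1,   FALSE, ""),
    list(21L, "FocalAreaDensity",        "A", TRUE,  FALSE, 0,   1,   FALSE, "t1"),
    list(22L, "FocalAdjT1",              "A", FALSE, TRUE,  0,   1,   FALSE, "t1"),
    list(23L, "FocalAdjT1andT2",         "A", FALSE, TRUE,  0,   1,   FALSE, "t1,t2"),
    list(24L, "FocalAdjT1givenT2",       "A", FALSE, TRUE,  0,   1,   FALSE, "t1,t2"),
    list(25L, "StandardDeviation",       "O", TRUE,  FALSE, 0,   100, FALSE, ""),
    list(26L, "CoefficientVariation",    "O", TRUE,  FALSE, NA,  NA,  FALSE, ""),
    list(27L, "Range",                   "O", TRUE,  FALSE, 0,   100, TRUE,  ""),
    list(28L, "Dissimilarity",           "O", FALSE, TRUE,  NA,  NA,  FALSE, ""),
    list(29L, "Contrast",                "O", FALSE, TRUE,  NA,  NA,  FALSE, ""),
    list(30L, "UniformityOrderedAdj",    "A", FALSE, TRUE,  0,   1,   FALSE, ""),
    list(31L, "UniformityUnorderedAdj",  "A", FALSE, TRUE,  0,   1,   FALSE, ""),
    list(32L, "Homogeneity",             "O", FALSE, TRUE,  0,   1,   FALSE, ""),
    list(33L, "InverseDifference",       "O", FALSE, TRUE,  0,   1,   FALSE, ""),
    list(34L, "SimilarityRMax",          "O", FALSE, TRUE,  0,   1,   FALSE, ""),
    list(35L, "SimilarityRGlobal",       "O", FALSE, TRUE,  0,   1,   FALSE, ""),
    list(36L, "SimilarityRWindow",       "O", FALSE, TRUE,  0,   1,   FALSE, ""),
    list(37L, "DominanceOrderedAdj",     "A", FALSE, TRUE,  0,   1,   FALSE, ""),
    list(38L, "DominanceUnorderedAdj",   "A", FALSE, TRUE,  0,   1,   FALSE, ""),
    list(39L, "DifferenceEntropy",       "O", FALSE, TRUE,  NA,  NA,  FALSE, ""),
    list(40L, "DifferenceEvenness",      "O", FALSE, TRUE,  0,   1,   FALSE, ""),
    list(41L, "SumEntropy",              "O", FALSE, TRUE,  NA,  NA,  FALSE, ""),
    list(42L, "SumEvenness",             "O", FALSE, TRUE,  0,   1,   FALSE, ""),
    list(43L, "AutoCorrelation",         "O", FALSE, TRUE,  NA,  NA,  FALSE, ""),
    list(44L, "Correlation",             "O", FALSE, TRUE,  -1,  1,   FALSE, ""),
    list(45L, "ClusterShade",            "O", FALSE, TRUE,  NA,  NA,  FALSE, ""),
    list(46L, "ClusterProminence",       "O", FALSE, TRUE,  NA,  NA,  FALSE, ""),
    list(47L, "RootMeanSquare",          "O", TRUE,  FALSE, NA,  NA,  FALSE, ""),
    list(48L, "AverageAbsDeviation",     "O", TRUE,  FALSE, NA,  NA,  FALSE, ""),
    list(49L, "kContagion",              "O", FALSE, TRUE,  0,   1,   FALSE, "kstar"),
    list(50L, "Skewness",                "O", TRUE,  FALSE, NA,  NA,  FALSE, ""),
    list(51L, "Kurtosis",                "O", TRUE,  FALSE, NA,  NA,  FALSE, "")
  )
  df <- do.call(rbind, lapply(rows, function(r)
    data.frame(id = r[[1L]], short_name = r[[2L]], input_type = r[[3L]],
               needs_freq = r[[4L]], needs_adj = r[[5L]],
               lower = r[[6L]], upper = r[[7L]], integer_out = r[[8L]],
               params = r[[9L]], stringsAsFactors = FALSE)))
  # which view of the tabulations the formula consumes
  df$tabulation <- c("frequency", "ordered", "unordered", "ordered",
                     "unordered", "ordered", "frequency", "frequency",
                     "frequency", "frequency", "frequency", "ordered",
                     "unordered", "ordered", "unordered", "frequency",
                     "frequency", "frequency", "frequency", "frequency",
                     "frequency", "unordered", "ordered", "unordered",
                     "frequency", "frequency", "frequency", "ordered",
                     "ordered", "ordered", "unordered", "ordered", "ordered",
                     "ordered", "ordered", "ordered", "ordered", "unordered",
                     "difference", "difference", "sum", "sum", "ordered",
                     "marginals", "ordered", "ordered", "frequency",
                     "frequency", "difference", "frequency", "frequency")
  df$bounded <- !is.na(df$lower)
  # byte output admits [0,1]-scaled and [0,100]/nominal integer-coded metrics
  df$byte_ok <- df$bounded & df$lower >= 0 & df$upper <= 103
  rownames(df) <- NULL
  df
}

.gsc_registry <- gsc_registry_build()

#' Catalogue of the 51 pattern metrics
#'
#' @return data.frame with one row per metric: `id` (1..51), `short_name`,
#'   `input_type` (`"A"` all, `"N"` nominal only, `"O"` ordinal only),
#'   `needs_freq`/`needs_adj` (which tabulation the metric consumes),
#'   `tabulation` (the derived view the formula reads: `frequency`,
#'   `ordered`, `unordered`, `marginals`, `difference` or `sum`),
#'   `lower`/`upper` output bounds (`NA` when unbounded), `integer_out`,
#'   `params` (required target parameters among `t1`, `t2`, `kstar`),
#'   `bounded` and `byte_ok` (eligible for 8-bit output).
#' @examples
#' m <- gsc_metrics()
#' nrow(m)               # 51
#' m$short_name[m$id == 10]
#' @export
gsc_metrics <- function() .gsc_registry

# Resolve a metric given by id or short name to its registry row.
gsc_metric_spec <- function(metric) {
  reg <- .gsc_registry
  if (is.character(metric)) {
    i <- match(metric, reg$short_name)
    if (is.na(i)) stop(sprintf("unknown metric name '%s'", metric))
    return(reg[i, ])
  }
  metric <- as.integer(metric)
  if (length(metric) != 1L || is.na(metric) || metric < 1L || metric > 51L)
    stop("metric id must be an integer in 1..51")
  reg[metric, ]
}

# Check the target parameters a metric requires; error on omission.
gsc_check_params <- function(spec, t1, t2, kstar) {
  need <- strsplit(spec$params, ",", fixed = TRUE)[[1L]]
  if ("t1" %in% need && is.null(t1))
    stop(sprintf("metric %d (%s) requires target gray level `t1`",
                 spec$id, spec$short_name))
  if ("t2" %in% need && is.null(t2))
    stop(sprintf("metric %d (%s) requires target gray level `t2`",
                 spec$id, spec$short_name))
  if ("kstar" %in% need && is.null(kstar))
    stop(sprintf("metric %d (%s) requires target difference level `kstar`",
                 spec$id, spec$short_name))
  if (!is.null(t1) && (t1 < 0L || t1 > 100L)) stop("`t1` must be in [0, 100]")
  if (!is.null(t2) && (t2 < 0L || t2 > 100L)) stop("`t2` must be in [0, 100]")
  if (!is.null(kstar) && (kstar < 0L || kstar > 100L))
    stop("`kstar` must be in [0, 100]")
  invisible(TRUE)
}
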