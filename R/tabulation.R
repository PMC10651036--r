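# Tabulations: the two statistical summaries every metric consumes.
#
# Both are kept as dense gray-level-indexed count structures (101 slots,
# levels 0..100) so the moving-window engine can add and subtract counts in
# O(1) per pixel/pair; derived quantities (proportions, marginals, moments,
# difference/sum distributions) are computed on demand from the counts.

#' Tabulate gray-level frequencies in a region
#'
#' Counts every non-missing pixel of the region once. Under
#' `exclude_zero = TRUE`, gray level 0 is treated as missing and dropped.
#'
#' @param raster a [gsc_raster()]
#' @param rows,cols integer vectors defining the rectangular region
#'   (defaults: whole raster)
#' @param exclude_zero drop gray level 0 from the tabulation?
#' @return object of class `gsc_freq`: list with `counts` (numeric length
#'   101, slot `i + 1` holds the count of level `i`) and `total`. A region
#'   with no countable pixels yields `total = 0`, which downstream
#'   evaluation turns into a missing metric value.
#' @export
gsc_tab_frequency <- function(raster, rows = NULL, cols = NULL,
                              exclude_zero = FALSE) {
  stopifnot(inherits(raster, "gsc_raster"))
  v <- raster$values
  if (is.null(rows)) rows <- seq_len(nrow(v))
  if (is.null(cols)) cols <- seq_len(ncol(v))
  if (any(rows < 1L | rows > nrow(v)) || any(cols < 1L | cols > ncol(v)))
    stop("region outside raster bounds")
  sub <- v[rows, cols, drop = FALSE]
  x <- sub[!is.na(sub)]
  if (exclude_zero) x <- x[x != 0L]
  counts <- numeric(101L)
  if (length(x)) {
    t <- tabulate(x + 1L, nbins = 101L)
    counts <- as.numeric(t)
  }
  structure(list(counts = counts, total = sum(counts)), class = "gsc_freq")
}

#' Tabulate gray-level adjacencies in a region
#'
#' Builds the ordered adjacency (co-occurrence) matrix under the 2-neighbor
#' rule: each pixel is paired with the pixel one below and the pixel one to
#' the right, and each adjacency is counted once, with the upper/left pixel
#' indexing the row and the lower/right pixel the column. A pair is counted
#' only if both pixels lie in the region, both are non-missing, and (under
#' `exclude_zero`) both are nonzero. A full R x C region with no missing
#' pixels therefore has `R*(C-1) + C*(R-1)` adjacencies.
#'
#' @inheritParams gsc_tab_frequency
#' @return object of class `gsc_adj`: list with `counts` (numeric 101 x 101
#'   ordered count matrix, level `i` at row `i + 1`) and `total`. A region
#'   with no countable pairs yields `total = 0`.
#' @export
gsc_tab_adjacency <- function(raster, rows = NULL, cols = NULL,
                              exclude_zero = FALSE) {
  stopifnot(inherits(raster, "gsc_raster"))
  v <- raster$values
  if (is.null(rows)) rows <- seq_len(nrow(v))
  if (is.null(cols)) cols <- seq_len(ncol(v))
  if (any(rows < 1L | rows > nrow(v)) || any(cols < 1L | cols > ncol(v)))
    stop("region outside raster bounds")
  sub <- v[rows, cols, drop = FALSE]
  if (exclude_zero) sub[!is.na(sub) & sub == 0L] <- NA_integer_
  nr <- nrow(sub); nc <- ncol(sub)
  A <- matrix(0, 101L, 101L)
  pair_acc <- function(a, b) {
    ok <- !is.na(a) & !is.na(b)
    if (any(ok)) {
      idx <- (b[ok]) * 101L + a[ok] + 1L  # column-major slot of [a+1, b+1]
      t <- tabulate(idx, nbins = 101L * 101L)
      A <<- A + matrix(t, 101L, 101L)
    }
  }
  if (nr > 1L)  # vertical: pixel over the one below
    pair_acc(as.vector(sub[-nr, , drop = FALSE]), as.vector(sub[-1L, , drop = FALSE]))
  if (nc > 1L)  # horizontal: pixel left of the one to the right
    pair_acc(as.vector(sub[, -nc, drop = FALSE]), as.vector(sub[, -1L, drop = FALSE]))
  structure(list(counts = A, total = sum(A)), class = "gsc_adj")
}

#' Collapse an ordered adjacency matrix to the unordered form
#'
#' The unordered matrix folds the ordered one across the main diagonal:
#' `x'(i, j) = x(i, j) + x(j, i)` for `j > i`, the diagonal is unchanged,
#' and the lower triangle is empty. Total mass is preserved.
#'
#' @param adj a `gsc_adj` from [gsc_tab_adjacency()]
#' @return 101 x 101 numeric upper-triangular count matrix.
#' @export
gsc_collapse_unordered <- function(adj) {
  stopifnot(inherits(adj, "gsc_adj"))
  A <- adj$counts
  U <- A + t(A)
  diag(U) <- diag(A)
  U[lower.tri(U)] <- 0
  U
}

#' Derived adjacency distributions
#'
#' Computes, from the ordered adjacency counts, the joint proportions
#' `p(i, j)`, unordered proportions `p'(i, j)`, row/column marginals with
#' their means and variances, and the gray-level difference and sum
#' distributions `p_[x-y](k)` (k = |i - j|) and `p_[x+y](k)` (k = i + j).
#'
#' @param adj a `gsc_adj` with `total > 0`
#' @return list with elements `p` (101 x 101), `p_unord` (upper triangle),
#'   `px`, `py` (length 101), `mu_x`, `mu_y`, `var_x`, `var_y`,
#'   `p_diff` (length 101, slot `k + 1`), `p_sum` (length 201, slot
#'   `k + 1`), `nk_diff`, `nk_sum` (numbers of nonzero k levels), `n_levels`
#'   (gray levels present in the matrix) and `range` (their span).
#' @export
gsc_adj_distributions <- function(adj) {
  stopifnot(inherits(adj, "gsc_adj"))
  if (adj$total <= 0) stop("adjacency tabulation is empty; distributions undefined")
  P <- adj$counts / adj$total
  lev <- 0:100
  px <- rowSums(P); py <- colSums(P)
  mu_x <- sum(lev * px); mu_y <- sum(lev * py)
  Pu <- P + t(P); diag(Pu) <- diag(P); Pu[lower.tri(Pu)] <- 0
  I <- matrix(lev, 101L, 101L); J <- t(I)
  p_diff <- as.vector(rowsum(as.vector(P), as.vector(abs(I - J))))
  p_sum <- as.vector(rowsum(as.vector(P), as.vector(I + J)))
  present <- (px + py) > 0
  list(p = P, p_unord = Pu, px = px, py = py,
       mu_x = mu_x, mu_y = mu_y,
       var_x = sum((lev - mu_x)^2 * px), var_y = sum((lev - mu_y)^2 * py),
       p_diff = p_diff, p_sum = p_sum,
       nk_diff = sum(p_diff > 0), nk_sum = sum(p_sum > 0),
       n_levels = sum(present),
       range = if (any(present)) diff(range(lev[present])) else NA_integer_)
}

# Frequency-side derived statistics (internal).
gsc_freq_stats <- function(freq) {
  lev <- 0:100
  p <- freq$counts / freq$total
  pos <- p > 0
  mu <- sum(lev * p)
  list(p = p, n_levels = sum(pos), mu = mu,
       var = sum((lev - mu)^2 * p),
       min_level = if (any(pos)) min(lev[pos]) else NA_integer_,
       max_level = if (any(pos)) max(lev[pos]) else NA_integer_)
}
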