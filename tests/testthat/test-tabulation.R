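test_that("frequency tabulation counts included pixels exactly once", {
  r <- gsc_raster(matrix(0:15, 4, 4))
  f <- gsc_tab_frequency(r)
  expect_equal(f$total, 16)

  # constant region of value 7
  rc <- gsc_raster(matrix(7L, 3, 3))
  fc <- gsc_tab_frequency(rc)
  expect_equal(fc$counts[8], 9)
  expect_equal(sum(fc$counts > 0), 1)

  # zero exclusion drops the zeros, keeps the rest
  rz <- gsc_raster(matrix(rep(c(0L, 100L), each = 50), 10, 10))
  fz <- gsc_tab_frequency(rz, exclude_zero = TRUE)
  expect_equal(fz$total, 50)
  expect_equal(sum(fz$counts > 0), 1)

  # empty included set signals downstream missing via total = 0
  expect_equal(gsc_tab_frequency(gsc_raster(matrix(NA_integer_, 2, 2)))$total, 0)
  expect_error(gsc_tab_frequency(r, rows = 1:9), "bounds")
})

test_that("adjacency tabulation follows the below/right 2-neighbor rule", {
  r <- gsc_raster(matrix(0:15, 4, 4))
  a <- gsc_tab_adjacency(r)
  expect_equal(a$total, 24)

  # 1x1 region has no neighbors
  expect_equal(gsc_tab_adjacency(r, rows = 2, cols = 2)$total, 0)

  # constant 3x3: 12 pairs, all on the diagonal slot
  ac <- gsc_tab_adjacency(gsc_raster(matrix(5L, 3, 3)))
  expect_equal(ac$total, 12)
  expect_equal(ac$counts[6, 6], 12)

  # ordered orientation: upper/left pixel is the row
  r2 <- gsc_raster(matrix(c(2L, 9L), 1, 2))
  a2 <- gsc_tab_adjacency(r2)
  expect_equal(a2$counts[3, 10], 1)
  expect_equal(a2$counts[10, 3], 0)

  # full R x C rectangle: R(C-1) + C(R-1) adjacencies
  for (d in list(c(2, 7), c(5, 5), c(3, 9), c(8, 2))) {
    rr <- gsc_fixture("random", d[1], d[2], levels = 0:30, seed = d[1] * d[2])
    expect_equal(gsc_tab_adjacency(rr)$total,
                 d[1] * (d[2] - 1) + d[2] * (d[1] - 1))
  }

  # a pair is dropped if either member is missing; survivors still count
  v <- matrix(4L, 3, 3); v[2, 2] <- NA
  am <- gsc_tab_adjacency(gsc_raster(v))
  expect_equal(am$total, 12 - 4)  # the 4 pairs through the center are gone
  fm <- gsc_tab_frequency(gsc_raster(v))
  expect_equal(fm$total, 8)
})

test_that("unordered collapse folds across the main diagonal", {
  A <- matrix(0, 101, 101)
  A[3, 6] <- 3; A[6, 3] <- 4; A[3, 3] <- 2
  adj <- structure(list(counts = A, total = sum(A)), class = "gsc_adj")
  U <- gsc_collapse_unordered(adj)
  expect_equal(U[3, 6], 7)   # x(2,5) + x(5,2)
  expect_equal(U[6, 3], 0)
  expect_equal(U[3, 3], 2)   # diagonal untouched
  expect_equal(sum(U), adj$total)

  # random matrix vs element-wise brute force
  set.seed(11)
  B <- matrix(0, 101, 101)
  B[1:10, 1:10] <- rpois(100, 2)
  adjB <- structure(list(counts = B, total = sum(B)), class = "gsc_adj")
  UB <- gsc_collapse_unordered(adjB)
  for (i in 1:10) for (j in 1:10) {
    want <- if (i == j) B[i, i] else if (j > i) B[i, j] + B[j, i] else 0
    expect_equal(UB[i, j], want)
  }

  # diagonal-only matrix is unchanged
  D <- matrix(0, 101, 101); diag(D)[4:6] <- 5
  adjD <- structure(list(counts = D, total = sum(D)), class = "gsc_adj")
  expect_equal(gsc_collapse_unordered(adjD), D)
})

test_that("derived distributions match direct pair enumeration and normalize", {
  # constant window: all difference mass at 0, all sum mass at 2v
  ac <- gsc_tab_adjacency(gsc_raster(matrix(6L, 4, 4)))
  d <- gsc_adj_distributions(ac)
  expect_equal(d$p_diff[1], 1)
  expect_equal(d$p_sum[13], 1)   # k = 12 at slot 13

  # perfect checkerboard: every pair differs by |a - b|
  cb <- gsc_fixture("checkerboard", 8, 8, levels = c(10, 90))
  dc <- gsc_adj_distributions(gsc_tab_adjacency(cb))
  expect_equal(dc$p_diff[81], 1)

  # random window: marginals and distributions against brute-force pairs
  r <- gsc_fixture("random", 20, 20, levels = c(0, 2, 5, 9, 40), seed = 4)
  adj <- gsc_tab_adjacency(r)
  d2 <- gsc_adj_distributions(adj)
  m <- r$values
  pa <- integer(0); pb <- integer(0)
  for (i in 1:19) for (j in 1:20) { pa <- c(pa, m[i, j]); pb <- c(pb, m[i + 1, j]) }
  for (i in 1:20) for (j in 1:19) { pa <- c(pa, m[i, j]); pb <- c(pb, m[i, j + 1]) }
  np <- length(pa)
  for (k in c(0, 2, 3, 5, 9, 38, 40)) {
    expect_equal(d2$p_diff[k + 1], sum(abs(pa - pb) == k) / np)
    expect_equal(d2$p_sum[k + 1], sum(pa + pb == k) / np)
  }
  for (l in c(0, 2, 5, 9, 40)) {
    expect_equal(d2$px[l + 1], sum(pa == l) / np)
    expect_equal(d2$py[l + 1], sum(pb == l) / np)
  }

  # normalization (within 1e-9) whenever mass is positive
  for (seed in 1:6) {
    rr <- gsc_fixture("random", 9, 9, levels = 0:15, missing_frac = 0.2,
                      seed = seed)
    aa <- gsc_tab_adjacency(rr)
    dd <- gsc_adj_distributions(aa)
    expect_equal(sum(dd$p), 1, tolerance = 1e-9)
    expect_equal(sum(dd$p_unord), 1, tolerance = 1e-9)
    expect_equal(sum(dd$p_diff), 1, tolerance = 1e-9)
    expect_equal(sum(dd$p_sum), 1, tolerance = 1e-9)
    expect_equal(sum(dd$px), 1, tolerance = 1e-9)
    expect_equal(sum(dd$py), 1, tolerance = 1e-9)
    # ordered and unordered agree on total mass and the diagonal
    expect_equal(diag(dd$p_unord), diag(dd$p))
  }
  expect_error(gsc_adj_distributions(
    gsc_tab_adjacency(gsc_raster(matrix(NA_integer_, 3, 3)))), "empty")
})

test_that("zero exclusion drops pairs touching a zero pixel", {
  v <- matrix(c(0L, 5L, 5L, 5L), 2, 2)
  a <- gsc_tab_adjacency(gsc_raster(v), exclude_zero = TRUE)
  expect_equal(a$total, 2)          # only the pairs among the three 5s survive
  expect_equal(a$counts[6, 6], 2)
  a0 <- gsc_tab_adjacency(gsc_raster(v), exclude_zero = FALSE)
  expect_equal(a0$total, 4)
})
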