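tab_pair <- function(raster, ...) {
  list(f = gsc_tab_frequency(raster, ...), a = gsc_tab_adjacency(raster, ...))
}

test_that("closed-form metric values on structured windows", {
  const <- tab_pair(gsc_raster(matrix(40L, 6, 6)))
  expect_equal(gsc_evaluate(1, freq = const$f), 40)               # Mean
  expect_equal(gsc_evaluate(6, adj = const$a), 1)                 # DiagonalContagion
  expect_equal(gsc_evaluate(29, adj = const$a), 0)                # Contrast
  expect_equal(gsc_evaluate(32, adj = const$a), 1)                # Homogeneity
  expect_equal(gsc_evaluate(34, adj = const$a), 1)                # SimilarityRMax
  expect_equal(gsc_evaluate(49, adj = const$a, kstar = 100L), 1)  # full mass
  expect_equal(gsc_evaluate(23, adj = const$a, t1 = 40L, t2 = 40L), 1)

  # two equally frequent levels: Gini-Simpson diversity 1 - 2*(1/2)^2
  cb <- tab_pair(gsc_fixture("checkerboard", 8, 8, levels = c(10, 90)))
  expect_equal(gsc_evaluate(10, freq = cb$f), 0.5)

  # equal p(i) over Ng > 1 maximizes Shannon evenness
  v <- gsc_raster(matrix(rep(c(3L, 7L, 9L, 20L), each = 4), 4, 4))
  eq <- tab_pair(v)
  expect_equal(gsc_evaluate(8, freq = eq$f), 1)
  expect_equal(gsc_evaluate(19, freq = eq$f), 4)   # NumberGrayLevels

  r3 <- gsc_raster(matrix(sample(c(3L, 7L, 9L), 36, TRUE), 6, 6))
  expect_equal(gsc_evaluate(19, freq = gsc_tab_frequency(r3)), 3)

  # symmetric frequency distribution has zero skewness
  sym <- gsc_raster(matrix(rep(c(10L, 20L, 30L), times = c(5, 8, 5)), 2, 9))
  expect_equal(gsc_evaluate(50, freq = gsc_tab_frequency(sym)), 0)
})

test_that("median and majority tie conventions are deterministic", {
  # even count: lower middle order statistic
  r <- gsc_raster(matrix(c(1L, 2L, 3L, 4L), 2, 2))
  expect_equal(gsc_evaluate(9, freq = gsc_tab_frequency(r)), 2)
  # majority ties resolve to the smallest tied level
  r2 <- gsc_raster(matrix(c(8L, 8L, 3L, 3L), 2, 2))
  expect_equal(gsc_evaluate(16, freq = gsc_tab_frequency(r2)), 3)
})

test_that("guard conditions yield missing values, parameter misuse errors", {
  const <- tab_pair(gsc_raster(matrix(40L, 5, 5)))
  for (id in c(2, 3, 8, 11, 12, 13))        # Ng > 1 guards
    expect_true(is.na(gsc_evaluate(id, freq = const$f, adj = const$a)))
  for (id in c(50, 51))                     # sigma > 0 guards
    expect_true(is.na(gsc_evaluate(id, freq = const$f)))
  expect_true(is.na(gsc_evaluate(44, adj = const$a)))   # sigma_x*sigma_y > 0
  expect_true(is.na(gsc_evaluate(36, adj = const$a)))   # window range 0
  expect_true(is.na(gsc_evaluate(40, adj = const$a)))   # Nk > 1
  expect_true(is.na(gsc_evaluate(42, adj = const$a)))
  # CV at mu = 0
  z <- tab_pair(gsc_raster(matrix(0L, 4, 4)))
  expect_true(is.na(gsc_evaluate(26, freq = z$f)))
  # zero denominator for conditional focal adjacency
  expect_true(is.na(gsc_evaluate(24, adj = const$a, t1 = 7L, t2 = 8L)))
  # empty tabulations are missing, not errors
  em <- tab_pair(gsc_raster(matrix(NA_integer_, 3, 3)))
  expect_true(is.na(gsc_evaluate(1, freq = em$f)))
  expect_true(is.na(gsc_evaluate(4, adj = em$a)))
  # caller mistakes raise
  expect_error(gsc_evaluate(52, freq = const$f), "1..51")
  expect_error(gsc_evaluate(21, freq = const$f), "t1")
  expect_error(gsc_evaluate(49, adj = const$a), "kstar")
  expect_error(gsc_evaluate(35, adj = const$a), "global_range")
})

test_that("registry catalogues all 51 metrics with their contracts", {
  reg <- gsc_metrics()
  expect_equal(nrow(reg), 51)
  expect_equal(reg$id, 1:51)
  expect_equal(reg$short_name[17], "LandscapeMosaic19")
  expect_equal(reg$short_name[2], "EvennessOrderedAdj")
  expect_equal(reg$short_name[3], "EvennessUnorderedAdj")
  expect_true(all(reg$needs_freq | reg$needs_adj))
  # the entropy/evenness pairs read different matrix views
  expect_equal(reg$tabulation[2], "ordered")
  expect_equal(reg$tabulation[3], "unordered")
  expect_equal(unname(reg$tabulation[c(39, 41)]), c("difference", "sum"))
  expect_true(all(reg$params[c(21, 22)] == "t1"))
  expect_equal(reg$params[49], "kstar")
  # name lookup and id lookup agree
  expect_equal(gsc_evaluate("Mean", freq = gsc_tab_frequency(
    gsc_raster(matrix(12L, 3, 3)))), 12)
})

test_that("compositional identities among metrics hold on random windows", {
  for (seed in 1:8) {
    r <- gsc_fixture("random", 12, 12, levels = sort(sample(0:100, 6)),
                     seed = seed, missing_frac = if (seed %% 2) 0.15 else 0)
    f <- gsc_tab_frequency(r); a <- gsc_tab_adjacency(r)
    Ng_f <- sum(f$counts > 0)
    d <- gsc_adj_distributions(a)
    ev <- function(id, ...) gsc_evaluate(id, freq = f, adj = a, ...)
    expect_equal(ev(8), ev(7) / log(Ng_f), tolerance = 1e-12)
    expect_equal(ev(2), ev(4) / (2 * log(d$n_levels)), tolerance = 1e-12)
    expect_equal(ev(40), ev(39) / log(d$nk_diff), tolerance = 1e-12)
    expect_equal(ev(42), ev(41) / log(d$nk_sum), tolerance = 1e-12)
    expect_equal(ev(14), 1 - ev(30), tolerance = 1e-12)
    expect_equal(ev(15), 1 - ev(31), tolerance = 1e-12)
    expect_equal(ev(11), ev(10) / (1 - 1 / Ng_f), tolerance = 1e-12)
  }
})

test_that("bounded metrics stay inside their declared bounds", {
  reg <- gsc_metrics()
  recipes <- list(
    gsc_fixture("random", 10, 10, levels = 0:100, seed = 1),
    gsc_fixture("random", 9, 11, levels = c(1, 2, 3), seed = 2),
    gsc_fixture("blocks", 12, 12, levels = c(0, 10, 55, 100), seed = 3),
    gsc_fixture("gradient", 8, 15),
    gsc_fixture("binned", 14, 14, levels = 0:20, seed = 4),
    gsc_fixture("random", 10, 10, levels = 0:5, missing_frac = 0.3, seed = 5))
  for (r in recipes) for (id in reg$id[reg$bounded]) {
    ps <- gsc_test_params(id, r)
    v <- gsc_global(r, id, t1 = ps$t1, t2 = ps$t2, kstar = ps$kstar)$value
    if (!is.na(v)) {
      expect_gte(v, reg$lower[id])
      expect_lte(v, reg$upper[id])
    }
  }
})

test_that("ordered vs unordered entropy obeys the symmetric-matrix identity", {
  # for symmetric ordered counts, H_unord = H_ord - p_offdiag * log(2)
  set.seed(21)
  for (trial in 1:5) {
    B <- matrix(0, 101, 101)
    k <- sample(3:8, 1)
    sub <- matrix(rpois(k * k, 3), k, k)
    sub <- sub + t(sub)                     # symmetric by construction
    B[1:k, 1:k] <- sub
    adj <- structure(list(counts = B, total = sum(B)), class = "gsc_adj")
    h_ord <- gsc_evaluate(4, adj = adj)
    h_unord <- gsc_evaluate(5, adj = adj)
    p_off <- 1 - gsc_evaluate(6, adj = adj)
    expect_equal(h_unord, h_ord - p_off * log(2), tolerance = 1e-12)
  }
})

test_that("kContagion is non-decreasing in k*, similarity metrics are ordered", {
  r <- gsc_fixture("random", 15, 15, levels = c(0, 5, 12, 30, 77), seed = 8)
  a <- gsc_tab_adjacency(r)
  kc <- vapply(0:100, function(k) gsc_evaluate(49, adj = a, kstar = k),
               numeric(1))
  expect_true(all(diff(kc) >= 0))
  expect_equal(kc[101], 1)

  # window range <= global range <= 100 implies similarity ordering
  m34 <- gsc_moving_window(r, 34, 5)$values
  m35 <- gsc_moving_window(r, 35, 5)$values
  m36 <- gsc_moving_window(r, 36, 5)$values
  ok <- !is.na(m36)
  expect_true(all(m34[ok] >= m35[ok] - 1e-12))
  expect_true(all(m35[ok] >= m36[ok] - 1e-12))
})

test_that("correlation matches brute-force summation over enumerated pairs", {
  r <- gsc_fixture("random", 15, 15, levels = c(2, 9, 15, 44, 80), seed = 13)
  a <- gsc_tab_adjacency(r)
  expect_equal(gsc_evaluate(44, adj = a), gsc_oracle(r, 44), tolerance = 1e-12)
  # bounded in [-1, 1]
  expect_lte(abs(gsc_evaluate(44, adj = a)), 1)
})
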