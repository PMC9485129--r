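test_that("layout produces contiguous regions with requested sizes", {
  lay <- synthetic_layout(262, c(0.4, 0.3, 0.3), seed = 3)
  sizes <- as.integer(table(lay$regions))
  expect_equal(sum(sizes), 262L)
  expect_true(all(abs(sizes - c(105, 79, 78)) <= 1))
  g <- build_delaunay_graph(lay$coords)
  for (r in 1:3) {
    nodes <- which(lay$regions == r)
    sub <- g$edges[g$edges[, 1] %in% nodes & g$edges[, 2] %in% nodes, ,
                   drop = FALSE]
    memb <- graphsv:::graph_components(make_graph(
      length(nodes), cbind(match(sub[, 1], nodes), match(sub[, 2], nodes))))
    expect_equal(max(memb), 1L)            # each region connected
  }
  expect_identical(synthetic_layout(100, seed = 9),
                   synthetic_layout(100, seed = 9))
  expect_equal(unique(synthetic_layout(40, c(1, 0, 0), seed = 1)$regions), 1L)
  expect_error(synthetic_layout(100, c(0.5, 0.2, 0.2)), "sum to 1")
})

test_that("region-mean genes have the prescribed means and determinism", {
  lay <- synthetic_layout(262, seed = 5)
  v <- simulate_sv_gene(lay$regions, sigma = 0.01, seed = 8)
  for (r in 1:3)
    expect_equal(mean(v[lay$regions == r]), r - 1, tolerance = 0.01)
  expect_identical(v, simulate_sv_gene(lay$regions, sigma = 0.01, seed = 8))
  # larger sigma swamps between-region differences relative to within-spread
  v_big <- simulate_sv_gene(lay$regions, sigma = 10, seed = 8)
  gap <- function(x) diff(range(tapply(x, lay$regions, mean)))
  expect_lt(gap(v_big) / sd(v_big), gap(v) / sd(v))
})

test_that("shuffling preserves the value multiset and is near-uniform", {
  v <- rnorm(50)
  s <- shuffle_gene(v, seed = 2)
  expect_equal(sort(s), sort(v))
  expect_identical(shuffle_gene(3.14, seed = 1), 3.14)
  # position 1 receives each of n values with frequency ~ 1/n
  n <- 8
  vals <- seq_len(n)
  first <- vapply(1:1000, function(s) shuffle_gene(vals, seed = s)[1],
                  numeric(1))
  freq <- tabulate(first, n) / 1000
  tol <- 3 * sqrt((1 / n) * (1 - 1 / n) / 1000)
  expect_true(all(abs(freq - 1 / n) <= tol))
})

test_that("perturbations behave as advertised", {
  v <- rnorm(100)
  expect_identical(perturb(v, "gaussian_noise", 0, seed = 1), v)
  expect_identical(perturb(v, "exchange", 0, seed = 1), v)

  big <- rnorm(1e4)
  noisy <- perturb(big, "gaussian_noise", 0.5, seed = 3)
  expect_equal(sd(noisy - big), 0.5, tolerance = 0.025)

  ex <- perturb(v, "exchange", 1, seed = 4)
  expect_equal(sort(ex), sort(v))
  expect_true(all(ex != v))               # full cyclic derangement
  half <- perturb(v, "exchange", 0.5, seed = 5)
  expect_equal(sum(half == v), 50)        # untouched spots keep their value
})

test_that("count transform allocates depth proportionally and inverts", {
  set.seed(60)
  n <- 262
  vals <- matrix(rnorm(n * 100, 1, 0.5), n, 100)
  depth <- rep(1e4, n)
  cnt <- to_counts(vals, depth, seed = 1)
  expect_true(all(cnt >= 0))
  expect_true(all(abs(rowSums(cnt) - depth) <= 100))  # per-gene rounding
  # uniform values, equal depths: near-equal expected counts
  cu <- to_counts(matrix(1, 30, 50), rep(5000, 30), seed = 2)
  expect_true(all(abs(cu - 100) <= 1))
  # +1 on the log2 scale doubles the within-spot count share
  v2 <- matrix(1, 5, 4); v2[, 2] <- 2
  c2 <- to_counts(v2, rep(6e3, 5), seed = 3)
  expect_equal(mean(c2[, 2]) / mean(c2[, 1]), 2, tolerance = 0.02)
  # round trip: normalize + log recovers the simulated values up to affine
  x <- SpatialExpression(synthetic_layout(n, seed = 60)$coords, cnt)
  rec <- log_transform(normalize_counts(x))$counts
  expect_gt(cor(as.vector(rec), as.vector(vals)), 0.95)
})

test_that("benchmark composition and determinism", {
  bm <- make_benchmark(n_sv = 5, n_null = 15, sigma = 0.3, seed = 77)
  expect_equal(dim(bm$matrix), c(262L, 20L))
  expect_equal(sum(bm$truth), 5L)
  expect_equal(bm$truth, rep(c(TRUE, FALSE), c(5, 15)))
  expect_false(bm$matrix$normalized)
  bm2 <- make_benchmark(n_sv = 5, n_null = 15, sigma = 0.3, seed = 77)
  expect_identical(bm$matrix$counts, bm2$matrix$counts)

  # nulls carry no spatial structure: region-mean gaps center on zero
  bmv <- make_benchmark(n_sv = 4, n_null = 40, sigma = 0.2, seed = 78,
                        counts = FALSE)
  gaps <- sapply(which(!bmv$truth), function(j)
    mean(bmv$matrix$counts[bmv$regions == 3, j]) -
      mean(bmv$matrix$counts[bmv$regions == 1, j]))
  expect_lt(abs(mean(gaps)), 0.15)
  sv_gaps <- sapply(which(bmv$truth), function(j)
    mean(bmv$matrix$counts[bmv$regions == 3, j]) -
      mean(bmv$matrix$counts[bmv$regions == 1, j]))
  expect_true(all(sv_gaps > 1.5))
})

test_that("parametric patterns partition coordinates sensibly", {
  lay <- synthetic_layout(200, seed = 4)
  for (p in c("bands", "strip", "disk", "quadrants", "annulus")) {
    reg <- pattern_regions(lay$coords, p)
    expect_equal(length(reg), 200L)
    expect_true(all(reg >= 1L))
    expect_gt(length(unique(reg)), 1L)
  }
  expect_equal(sort(unique(pattern_regions(lay$coords, "quadrants"))), 1:4)
  expect_equal(max(pattern_regions(lay$coords, "bands", k = 3)), 3L)

  # a custom layout drives the benchmark through the layout hook
  custom <- list(coords = lay$coords,
                 regions = pattern_regions(lay$coords, "strip"))
  bm <- make_benchmark(n_sv = 3, n_null = 3, sigma = 0.2, counts = FALSE,
                       layout = custom, region_means = c(0, 2), seed = 6)
  expect_equal(dim(bm$matrix)[1], 200L)
  v <- bm$matrix$counts[, 1]
  expect_gt(mean(v[custom$regions == 2]) - mean(v[custom$regions == 1]), 1.5)
})
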