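test_that("confusion metrics reproduce the closed-form definitions", {
  truth <- rep(c(TRUE, FALSE), c(10, 90))
  called <- c(rep(TRUE, 8), FALSE, FALSE, TRUE, rep(FALSE, 89))
  m <- confusion_metrics(truth, called)
  expect_equal(m[c("TP", "FN", "FP", "TN")], list(TP = 8L, FN = 2L,
                                                  FP = 1L, TN = 89L))
  expect_equal(m$accuracy, 0.97)
  expect_equal(m$sensitivity, 0.8)
  expect_equal(m$fpr, 0.011111, tolerance = 1e-4)
  expect_equal(m$f1, 0.842105, tolerance = 1e-6)

  perfect <- confusion_metrics(truth, truth)
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$fpr, 0)
  expect_equal(confusion_metrics(truth, rep(FALSE, 100))$sensitivity, 0)
  expect_true(confusion_metrics(rep(TRUE, 5), rep(TRUE, 5))$degenerate)
})

test_that("points map to layers by containment with first-match ties", {
  sq1 <- cbind(c(0, 1, 1, 0), c(0, 0, 1, 1))       # unit square
  sq2 <- cbind(c(1, 2, 2, 1), c(0, 0, 1, 1))       # adjacent square
  pts <- rbind(c(0.5, 0.5), c(1.5, 0.5), c(5, 5), c(1, 0.5))
  lab <- assign_points_to_layers(pts, list(sq1, sq2))
  expect_equal(lab[1], 1L)
  expect_equal(lab[2], 2L)
  expect_true(is.na(lab[3]))
  expect_equal(lab[4], 1L)                          # shared edge: first layer

  # analytic split of a grid between two half-plane rectangles
  grid <- as.matrix(expand.grid(x = seq(0.05, 1.95, by = 0.1),
                                y = seq(0.05, 0.95, by = 0.1)))
  lab2 <- assign_points_to_layers(grid, list(sq1, sq2))
  expect_equal(sum(lab2 == 1), sum(grid[, 1] < 1))
  expect_equal(sum(lab2 == 2), sum(grid[, 1] > 1))

  # per-spot label vector passes through
  expect_equal(assign_points_to_layers(pts, c(2L, 1L, 3L, 1L)),
               c(2L, 1L, 3L, 1L))
})

test_that("segments match layers by maximum overlap", {
  u1 <- c(rep(1, 10), rep(0, 10))
  u2 <- c(rep(0, 10), rep(1, 10))
  expect_equal(match_segments_to_layers(list(u1), list(u1, u2))$layer, 1L)
  v <- c(rep(1, 7), rep(0, 3), rep(1, 3), rep(0, 7))   # 7 in A, 3 in B
  expect_equal(match_segments_to_layers(list(v), list(u1, u2))$layer, 1L)
  none <- rep(0, 20)
  m <- match_segments_to_layers(list(none), list(u1, u2))
  expect_equal(m$layer, 1L)
  expect_true(m$no_overlap)
})

test_that("normalized Hamming distance reproduces worked values", {
  u6 <- rep(c(1, 0), c(6, 4))
  expect_equal(normalized_hamming(u6, u6), 0)
  u <- c(1, 1, 1, 1, 0, 0); v <- c(1, 1, 0, 0, 1, 1)
  expect_equal(normalized_hamming(u, v), 4 / 12, tolerance = 1e-6)
  a <- c(1, 1, 1, 0, 0, 0); b <- c(0, 0, 0, 1, 1, 1)
  expect_equal(normalized_hamming(a, b), 0.6)
  expect_equal(normalized_hamming(a, b), normalized_hamming(b, a))
})

test_that("jaccard and hausdorff distances follow their definitions", {
  coords <- cbind(c(0, 3, 0, 3, 10), c(0, 0, 4, 4, 0))
  u <- c(1, 1, 0, 0, 0)
  d0 <- structure_distances(u, u, coords)
  expect_equal(d0$jaccard, 0)
  expect_equal(d0$hausdorff, 0)
  v <- c(0, 0, 1, 1, 0)
  dd <- structure_distances(u, v, coords)
  expect_equal(dd$jaccard, 1)
  one_a <- c(1, 0, 0, 0, 0); one_b <- c(0, 0, 0, 0, 1)
  expect_equal(structure_distances(one_a, one_b, coords)$hausdorff, 10)
  de <- structure_distances(u, rep(0, 5), coords)
  expect_true(de$hausdorff_degenerate)
  expect_equal(de$jaccard, 1)
})

test_that("tissue reconstruction recovers strong synthetic regions", {
  bm <- make_benchmark(n_sv = 40, n_null = 0, sigma = 0.1, seed = 91,
                       counts = FALSE)
  x <- bm$matrix
  g <- build_delaunay_graph(x$coords)
  expect_equal(reconstruct_tissue(x, x$gene_ids, g, k = 1),
               rep(1L, 262))
  km_only <- reconstruct_tissue(x, x$gene_ids, g, k = 3, alpha = 0, seed = 5)
  set.seed(5)
  km <- kmeans(x$counts, centers = 3, nstart = 10, iter.max = 100)
  expect_equal(km_only, as.integer(km$cluster))

  rec <- reconstruct_tissue(x, x$gene_ids, g, k = 3, seed = 5)
  expect_gte(overlap_accuracy(rec, bm$regions), 0.9)

  # degradation with noise: sigma = 0.6 does no better than sigma = 0.1
  bm6 <- make_benchmark(n_sv = 40, n_null = 0, sigma = 0.6, seed = 91,
                        counts = FALSE)
  rec6 <- reconstruct_tissue(bm6$matrix, bm6$matrix$gene_ids, g, k = 3,
                             seed = 5)
  expect_lte(overlap_accuracy(rec6, bm6$regions),
             overlap_accuracy(rec, bm$regions))
  expect_error(reconstruct_tissue(x, "nope", g, k = 2), "not present")
})

test_that("overlap accuracy handles permuted and degenerate labelings", {
  truth <- rep(1:3, each = 10)
  pred <- rep(c(3L, 1L, 2L), each = 10)
  expect_equal(overlap_accuracy(pred, truth), 1)
  expect_equal(overlap_accuracy(pred, truth, optimal = TRUE), 1)
  expect_equal(overlap_accuracy(rep(1L, 30), truth), 1 / 3)
})

test_that("distance thresholds are reference-distribution quantiles", {
  d <- seq(0, 1, length.out = 101)
  expect_equal(distance_threshold(d, 0.95), 0.95)
  expect_equal(distance_threshold(d, 1), 1)
  expect_error(distance_threshold(d, 0))
})
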