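test_that("interaction matrix follows the ordinal metric form", {
  expect_equal(interaction_matrix(3, 1),
               rbind(c(0, 1, 2), c(1, 0, 1), c(2, 1, 0)))
  expect_equal(interaction_matrix(2, 2.5), rbind(c(0, 2.5), c(2.5, 0)))
  S <- interaction_matrix(5, 0.7)
  for (i in 1:5) for (j in 1:5) for (k in 1:5)
    expect_lte(S[i, k], S[i, j] + S[j, k] + 1e-12)
})

test_that("total energy sums unary and once-per-edge pairwise terms", {
  g <- make_graph(2, cbind(1, 2))
  U0 <- matrix(0, 2, 2)
  expect_equal(total_energy(g, c(1, 2), U0, interaction_matrix(2, 1), 2), 2)
  set.seed(1)
  U <- matrix(runif(6), 2, 3)
  expect_equal(total_energy(g, c(3, 1), U, interaction_matrix(3, 1), 0),
               U[1, 3] + U[2, 1])
  g1 <- make_graph(1, matrix(integer(0), 0, 2))
  expect_equal(total_energy(g1, 2, matrix(c(0.3, 0.8), 1),
                            interaction_matrix(2, 1), 5), 0.8)
})

test_that("min_cut attains the exhaustive minimum on random instances", {
  r <- min_cut(3, 5)
  expect_equal(r$value, 3)
  expect_equal(r$assignment, 1L)

  set.seed(21)
  for (trial in 1:100) {
    m <- sample(2:10, 1)
    src <- runif(m, 0, 4); snk <- runif(m, 0, 4)
    npairs <- sample(1:(2 * m), 1)
    pairs <- cbind(sample(m, npairs, TRUE), sample(m, npairs, TRUE),
                   runif(npairs, 0, 3), runif(npairs, 0, 3))
    pairs <- pairs[pairs[, 1] != pairs[, 2], , drop = FALSE]
    r <- min_cut(src, snk, pairs)
    expect_equal(r$value, brute_force_min_cut(src, snk, pairs),
                 tolerance = 1e-9)
  }
  expect_error(min_cut(-1, 2), "non-negative")
})

test_that("alpha-expansion with no smoothing decouples into row minima", {
  set.seed(2)
  g <- random_connected_graph(8, seed = 2)
  U <- matrix(runif(8 * 3), 8, 3)
  lf <- alpha_expansion(g, U, interaction_matrix(3, 1), alpha = 0,
                        init = rep(1L, 8))
  expect_equal(lf$labels, max.col(-U, ties.method = "first"))
})

test_that("two-label expansion is globally optimal (exhaustive oracle)", {
  set.seed(3)
  for (trial in 1:20) {
    n <- sample(4:10, 1)
    g <- random_connected_graph(n, seed = trial + 300)
    U <- matrix(runif(n * 2, 0, 3), n, 2)
    alpha <- runif(1, 0.1, 2)
    S <- interaction_matrix(2, runif(1, 0.2, 2))
    lf <- alpha_expansion(g, U, S, alpha, init = sample(1:2, n, TRUE))
    expect_equal(lf$energy, brute_force_min_energy(g, U, S, alpha),
                 tolerance = 1e-9)
    expect_equal(lf$energy, total_energy(g, lf$labels, U, S, alpha))
  }
})

test_that("huge smoothing yields the best uniform labeling", {
  set.seed(4)
  g <- random_connected_graph(6, seed = 44)
  U <- matrix(runif(18), 6, 3)
  S <- interaction_matrix(3, 1)
  lf <- alpha_expansion(g, U, S, alpha = 1e6, init = sample(1:3, 6, TRUE))
  best_uniform <- which.min(colSums(U))
  expect_equal(lf$labels, rep(best_uniform, 6))
  expect_error(alpha_expansion(g, U, matrix(1, 3, 3), 1, rep(1L, 6)),
               "regularity")
})

test_that("expansion energy never increases and beats reference labelings", {
  set.seed(5)
  for (trial in 1:10) {
    n <- 15
    g <- random_connected_graph(n, seed = trial + 500)
    K <- sample(3:5, 1)
    U <- matrix(runif(n * K, 0, 2), n, K)
    S <- interaction_matrix(K, 0.5)
    alpha <- runif(1, 0, 3)
    init <- sample(seq_len(K), n, TRUE)
    lf <- alpha_expansion(g, U, S, alpha, init)
    expect_lte(lf$energy, total_energy(g, init, U, S, alpha) + 1e-9)
    for (k in seq_len(K))
      expect_lte(lf$energy,
                 total_energy(g, rep(k, n), U, S, alpha) + 1e-9)
  }
})

test_that("segments partition the graph into uniform connected components", {
  path <- make_graph(3, rbind(c(1, 2), c(2, 3)))
  seg <- extract_segments(path, c(1, 2, 1))
  expect_equal(length(seg$segments), 3L)
  expect_equal(nrow(seg$boundary_edges), 2L)

  g <- make_graph(4, rbind(c(1, 2), c(2, 3), c(3, 4), c(1, 4)))
  uni <- extract_segments(g, rep(2L, 4))
  expect_equal(length(uni$segments), 1L)
  expect_equal(sort(uni$segments[[1]]$nodes), 1:4)
  expect_equal(nrow(uni$boundary_edges), 0L)

  set.seed(6)
  gr <- random_connected_graph(20, seed = 66)
  for (rep in 1:5) {
    labels <- sample(1:3, 20, TRUE)
    s <- extract_segments(gr, labels)
    nodes <- sort(unlist(lapply(s$segments, `[[`, "nodes")))
    expect_equal(nodes, 1:20)                      # exact partition
    for (sg in s$segments)
      expect_equal(length(unique(labels[sg$nodes])), 1L)
    # adjacent segments differ in label: every boundary edge is discordant
    if (nrow(s$boundary_edges))
      expect_true(all(labels[s$boundary_edges[, 1]] !=
                        labels[s$boundary_edges[, 2]]))
  }
})

test_that("the signal-to-noise score matches its closed form", {
  expect_equal(score_segmentation(1e-5, 0, 262), 5)
  expect_equal(score_segmentation(0.01, 2, 400), 1)
  expect_equal(score_segmentation(1, 0, 100), 0)
  # strictly decreasing in p and in noise count
  expect_gt(score_segmentation(1e-6, 1, 200), score_segmentation(1e-4, 1, 200))
  expect_gt(score_segmentation(0.01, 0, 200), score_segmentation(0.01, 3, 200))
})

test_that("smooth-factor search stops on worsening score and keeps the best", {
  bm <- make_benchmark(n_sv = 3, n_null = 1, sigma = 0.1, n_spots = 120,
                       seed = 31, counts = FALSE)
  x <- bm$matrix
  g <- build_delaunay_graph(x$coords)
  for (j in 1:3) {
    v <- x$counts[, j]
    gmm <- select_gmm(v, seed = 1)
    obs <- initial_labels(gmm, v)
    sr <- search_smooth_factor(g, data_penalties(v, gmm),
                               interaction_matrix(gmm$K, 0.1), obs)
    expect_true(all(diff(sr$trace$alpha) > 0))
    expect_equal(sr$best_score, max(sr$trace$score))
    expect_equal(sr$best_alpha, sr$trace$alpha[which.max(sr$trace$score)])
    # stopped at the first strictly-worse score (or exhausted the grid)
    worse <- which(diff(sr$trace$score) < 0)
    if (length(worse))
      expect_equal(nrow(sr$trace), worse[1] + 1L)
    # the best segmentation recovers a true region closely
    seg_sets <- lapply(sr$best_segmentation$segments, `[[`, "nodes")
    big <- seg_sets[[which.max(lengths(seg_sets))]]
    jac <- min(sapply(1:3, function(r) {
      truthset <- which(bm$regions == r)
      1 - length(intersect(big, truthset)) / length(union(big, truthset))
    }))
    expect_lt(jac, 0.2)
  }
})
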