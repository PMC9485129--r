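# Shared fixtures and independent oracles. Oracles here are deliberately
# naive (enumeration, summed series, hand step-up) and independent of the
# package implementation paths they check.

# minimal NeighborGraph over an explicit edge list (no geometry needed)
make_graph <- function(n, edges, coords = NULL) {
  edges <- matrix(as.integer(edges), ncol = 2L)
  edges <- cbind(pmin(edges[, 1L], edges[, 2L]),
                 pmax(edges[, 1L], edges[, 2L]))
  if (is.null(coords)) coords <- cbind(seq_len(n), 0)
  structure(list(n = n, edges = edges,
                 adjacency = graphsv:::edges_to_adjacency(edges, n),
                 coords = coords, voronoi = NULL),
            class = "NeighborGraph")
}

random_connected_graph <- function(n, seed) {
  set.seed(seed)
  # random spanning tree plus extra random edges
  perm <- sample(n)
  tree <- cbind(perm[-1L], perm[vapply(2:n, function(i) sample(i - 1L, 1L),
                                       1L)])
  extra <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  extra <- extra[sample(nrow(extra), min(nrow(extra), n)), , drop = FALSE]
  e <- rbind(tree, extra)
  e <- unique(cbind(pmin(e[, 1L], e[, 2L]), pmax(e[, 1L], e[, 2L])))
  make_graph(n, e)
}

# exhaustive minimum of the labeling energy over all K^n configurations
brute_force_min_energy <- function(g, U, S, alpha) {
  n <- g$n
  K <- ncol(U)
  best <- Inf
  labels <- rep(1L, n)
  repeat {
    e <- total_energy(g, labels, U, S, alpha)
    if (e < best) best <- e
    i <- 1L
    while (i <= n) {
      labels[i] <- labels[i] + 1L
      if (labels[i] <= K) break
      labels[i] <- 1L
      i <- i + 1L
    }
    if (i > n) break
  }
  best
}

# brute-force s-t min cut: enumerate all 2^m side assignments
brute_force_min_cut <- function(src, snk, pairs) {
  m <- length(src)
  best <- Inf
  for (mask in 0:(2^m - 1)) {
    b <- as.integer(intToBits(mask))[seq_len(m)]  # 1 = sink side
    cost <- sum(src[b == 1L]) + sum(snk[b == 0L])
    if (!is.null(pairs) && nrow(pairs)) {
      for (r in seq_len(nrow(pairs))) {
        i <- pairs[r, 1L]; j <- pairs[r, 2L]
        if (b[i] == 0L && b[j] == 1L) cost <- cost + pairs[r, 3L]
        if (b[i] == 1L && b[j] == 0L) cost <- cost + pairs[r, 4L]
      }
    }
    if (cost < best) best <- cost
  }
  best
}

# summed-PMF Poisson upper tail, independent of ppois
poisson_tail_oracle <- function(k, lam) {
  if (k == 0) return(1)
  1 - sum(exp(-lam) * lam^(0:(k - 1)) / factorial(0:(k - 1)))
}

# textbook step-up BH
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  prev <- 1
  for (i in m:1) {
    prev <- min(prev, p[o[i]] * m / i)
    q[o[i]] <- prev
  }
  q
}

tiny_sem <- function() {
  SpatialExpression(
    coords = rbind(c(1, 1), c(1, 2), c(2, 1)),
    counts = rbind(c(2, 8), c(5, 15), c(10, 30)),
    spot_ids = c("1x1", "1x2", "2x1"),
    gene_ids = c("geneA", "geneB"))
}
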