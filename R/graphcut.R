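#' Ordinal interaction energy matrix
#'
#' The pairwise smoothing term of the segmentation energy. States are
#' ordered by expression level, so the penalty for two neighboring spots
#' grows with the distance between their state indices:
#' `S[i, j] = |i - j| * penalty_factor`. Being a metric (zero diagonal,
#' symmetric, triangle inequality), this matrix is regular for every binary
#' subproblem, which is what makes exact graph-cut expansion moves possible.
#'
#' @param K number of states.
#' @param penalty_factor positive magnitude factor (default 1; the smooth
#'   factor `alpha` absorbs overall scale, so this rarely needs changing).
#' @return A K x K symmetric matrix with zero diagonal.
#' @export
interaction_matrix <- function(K, penalty_factor = 1) {
  stopifnot(K >= 1, penalty_factor > 0)
  idx <- seq_len(K)
  abs(outer(idx, idx, "-")) * penalty_factor
}

#' Total segmentation energy
#'
#' `E(X) = sum_p U[p, x_p] + alpha * sum_{(p,q) in edges} S[x_p, x_q]`,
#' each undirected edge counted once. This is the objective that
#' alpha-expansion minimizes; lower energy means labels fit the data better
#' while varying less across edges.
#'
#' @param g a [NeighborGraph].
#' @param labels integer labels in `1..K`, length `g$n`.
#' @param U n x K data penalty matrix ([data_penalties()]).
#' @param S K x K interaction matrix ([interaction_matrix()]).
#' @param alpha non-negative smooth factor.
#' @return The scalar energy.
#' @export
total_energy <- function(g, labels, U, S, alpha) {
  labels <- as.integer(labels)
  stopifnot(length(labels) == g$n, all(labels >= 1L), all(labels <= ncol(U)))
  e <- sum(U[cbind(seq_len(g$n), labels)])
  if (nrow(g$edges))
    e <- e + alpha * sum(S[cbind(labels[g$edges[, 1L]], labels[g$edges[, 2L]])])
  e
}

#' Exact binary minimum s-t cut
#'
#' Solves the two-label energy minimization at the heart of every expansion
#' move: given per-node severance costs toward source and sink and directed
#' pairwise capacities, returns a globally minimal s-t cut (via max-flow;
#' min-cut/max-flow duality makes the two-label problem exactly solvable).
#' A node assigned side 1 (sink side) severs its source capacity; side 0
#' severs its sink capacity; a pair edge `i -> j` is severed when `i` is on
#' side 0 and `j` on side 1.
#'
#' @param source_capacities,sink_capacities numeric vectors of length m,
#'   non-negative.
#' @param pair_capacities `NULL` or a 4-column matrix/data frame
#'   `(i, j, cap_ij, cap_ji)` of non-negative directed capacities.
#' @return A list with `assignment` (integer vector, 0 = source side,
#'   1 = sink side) and `value` (the minimal cut cost).
#' @export
min_cut <- function(source_capacities, sink_capacities, pair_capacities = NULL) {
  m <- length(source_capacities)
  stopifnot(length(sink_capacities) == m)
  if (any(source_capacities < 0) || any(sink_capacities < 0))
    stop("capacities must be non-negative")
  pi <- pj <- integer(0); pcap <- numeric(0)
  if (!is.null(pair_capacities) && NROW(pair_capacities) > 0) {
    pc <- as.matrix(pair_capacities)
    if (any(pc[, 3:4] < 0)) stop("capacities must be non-negative")
    pi <- c(pc[, 1L], pc[, 2L]); pj <- c(pc[, 2L], pc[, 1L])
    pcap <- c(pc[, 3L], pc[, 4L])
  }
  s <- m + 1L; t <- m + 2L
  from <- c(rep(s, m), seq_len(m), pi)
  to <- c(seq_len(m), rep(t, m), pj)
  cap <- c(source_capacities, sink_capacities, pcap)
  nz <- cap > 0
  ig <- igraph::make_empty_graph(n = m + 2L, directed = TRUE)
  if (any(nz))
    ig <- igraph::add_edges(ig, rbind(from[nz], to[nz]))
  mf <- igraph::max_flow(ig, source = s, target = t,
                         capacity = if (any(nz)) cap[nz] else numeric(0))
  assignment <- integer(m)
  sink_side <- setdiff(as.integer(mf$partition2), t)
  assignment[sink_side] <- 1L
  list(assignment = assignment, value = mf$value)
}

check_regular <- function(S) {
  if (any(diag(S) != 0))
    stop("interaction energy violates regularity: nonzero diagonal")
  K <- nrow(S)
  if (!isTRUE(all.equal(S, t(S))))
    stop("interaction energy violates regularity: not symmetric")
  for (a in seq_len(K)) {
    # expansion toward label a is submodular iff S[i,a] + S[a,j] >= S[i,j]
    if (any(outer(S[, a], S[a, ], "+") - S < -1e-12))
      stop("interaction energy violates regularity: ",
           "triangle inequality fails for label ", a)
  }
  invisible(TRUE)
}

acc_by_index <- function(idx, val, n) {
  out <- numeric(n)
  if (length(idx)) {
    r <- rowsum(val, idx)
    out[as.integer(rownames(r))] <- r
  }
  out
}

expansion_move <- function(labels, a, edges, U, S, alpha) {
  n <- length(labels)
  theta1 <- U[, a]                          # cost of switching to a
  theta0 <- U[cbind(seq_len(n), labels)]    # cost of keeping current label
  const <- 0
  pi <- pj <- integer(0); pcap <- numeric(0)
  if (nrow(edges)) {
    p <- edges[, 1L]; q <- edges[, 2L]
    A <- alpha * S[cbind(labels[p], labels[q])]  # keep, keep
    B <- alpha * S[cbind(labels[p], rep.int(a, length(p)))]  # keep, switch
    C <- alpha * S[cbind(rep.int(a, length(q)), labels[q])]  # switch, keep
    # pairwise term E(b_p, b_q) = A + (C - A) b_p - C b_q + (B + C - A)[b_p=0, b_q=1]
    theta1 <- theta1 + acc_by_index(p, C - A, n) + acc_by_index(q, -C, n)
    const <- const + sum(A)
    cap <- B + C - A                         # >= 0 by regularity
    keep <- cap > 0
    pi <- p[keep]; pj <- q[keep]; pcap <- cap[keep]
  }
  shift <- pmin(theta0, theta1)
  theta0 <- theta0 - shift
  theta1 <- theta1 - shift
  const <- const + sum(shift)

  s <- n + 1L; t <- n + 2L
  from <- c(rep(s, n), seq_len(n), pi)
  to <- c(seq_len(n), rep(t, n), pj)
  cap_all <- c(theta1, theta0, pcap)
  nz <- cap_all > 0
  ig <- igraph::make_empty_graph(n = n + 2L, directed = TRUE)
  if (any(nz)) ig <- igraph::add_edges(ig, rbind(from[nz], to[nz]))
  mf <- igraph::max_flow(ig, source = s, target = t,
                         capacity = if (any(nz)) cap_all[nz] else numeric(0))
  switch_to_a <- setdiff(as.integer(mf$partition2), t)
  new_labels <- labels
  new_labels[switch_to_a] <- a
  list(labels = new_labels, energy_bound = const + mf$value)
}

#' Multi-label energy minimization by alpha-expansion
#'
#' Minimizes the segmentation energy ([total_energy()]) by iteratively
#' applying exact two-label graph cuts: each expansion move lets every node
#' either keep its current label or switch to the candidate label, and the
#' globally optimal such move is found by [min_cut()]. Labels are visited in
#' ascending order each sweep; a move is accepted only if it strictly
#' decreases the energy, and the algorithm stops when a full sweep makes no
#' move (or after `max_sweeps` sweeps). For two labels the result is the
#' global minimum; for more labels the multi-label problem is NP-hard and
#' the result is a strong local minimum within a known factor of the global
#' optimum.
#'
#' @param g a [NeighborGraph].
#' @param U n x K data penalty matrix.
#' @param S K x K regular interaction matrix (checked; overriding with a
#'   non-metric matrix is refused).
#' @param alpha non-negative smooth factor.
#' @param init integer initial labels in `1..K`.
#' @param max_sweeps maximum number of full sweeps over the label set.
#' @return An object of class `LabelField`: list with `labels`, `energy`
#'   (equal to `total_energy()` of the labels), `alpha`, `sweeps`.
#' @export
alpha_expansion <- function(g, U, S, alpha, init, max_sweeps = 10L) {
  K <- ncol(U)
  labels <- as.integer(init)
  stopifnot(length(labels) == g$n, all(labels >= 1L), all(labels <= K))
  if (alpha < 0) stop("'alpha' must be non-negative")
  check_regular(S)
  energy <- total_energy(g, labels, U, S, alpha)
  init_energy <- energy
  sweeps <- 0L
  for (sw in seq_len(max_sweeps)) {
    sweeps <- sw
    moved <- FALSE
    for (a in seq_len(K)) {
      mv <- expansion_move(labels, a, g$edges, U, S, alpha)
      new_energy <- total_energy(g, mv$labels, U, S, alpha)
      if (new_energy < energy - 1e-9) {
        labels <- mv$labels
        energy <- new_energy
        moved <- TRUE
      }
    }
    if (!moved) break
  }
  stopifnot(energy <= init_energy + 1e-9)
  structure(list(labels = labels, energy = energy, alpha = alpha,
                 sweeps = sweeps),
            class = "LabelField")
}

#' Extract segments from a label field
#'
#' Segments are the connected components of the subgraph induced by
#' same-label edges: maximal connected regions of identical hidden label.
#' These are the candidate regions tested for spatial non-randomness.
#'
#' @param g a [NeighborGraph].
#' @param labels integer labels of length `g$n`.
#' @return An object of class `Segmentation`: list with `segments` (each a
#'   list with `nodes` and `label`), `boundary_edges` (label-discordant
#'   edges), `n`, and the input `labels`.
#' @export
extract_segments <- function(g, labels) {
  labels <- as.integer(labels)
  stopifnot(length(labels) == g$n)
  same <- if (nrow(g$edges))
    labels[g$edges[, 1L]] == labels[g$edges[, 2L]] else logical(0)
  memb <- graph_components(g, g$edges[same, , drop = FALSE])
  segs <- lapply(split(seq_len(g$n), memb), function(nodes)
    list(nodes = nodes, label = labels[nodes[1L]]))
  names(segs) <- NULL
  structure(list(segments = segs,
                 boundary_edges = g$edges[!same, , drop = FALSE],
                 n = g$n, labels = labels),
            class = "Segmentation")
}

#' @exportS3Method print Segmentation
print.Segmentation <- function(x, ...) {
  cat("Segmentation:", length(x$segments), "segments over", x$n, "nodes\n")
  invisible(x)
}

#' Signal-to-noise score of a segmentation
#'
#' `score = -log10(best_p) - n_noise_segments * 200 / n`, where `best_p` is
#' the segmentation's spatial non-randomness p-value and noise segments are
#' segments with at most 9 nodes and p >= 0.1. The second term is the noise
#' segment count normalized to a 200-node graph. The score drives the
#' smooth-factor search: it rewards strong spatial signal and penalizes
#' fragmented, insignificant speckle.
#'
#' @param best_p the segmentation's best segment p-value, in (0, 1].
#' @param n_noise_segments number of noise segments (counted by the caller).
#' @param n number of nodes in the graph.
#' @return The scalar score.
#' @export
score_segmentation <- function(best_p, n_noise_segments, n) {
  stopifnot(n > 0, best_p >= 0, best_p <= 1, n_noise_segments >= 0)
  -log10(max(best_p, 1e-300)) - n_noise_segments * (200 / n)
}

#' Sequential smooth-factor search
#'
#' The smooth factor `alpha` is the one free hyperparameter of the
#' segmentation energy. This heuristic search evaluates
#' `alpha = start, start + step, ...` (capped at `max_alpha`); at each value
#' it runs [alpha_expansion()] from the GMM initial labels, extracts
#' segments, computes every segment's CSR p-value against the fixed observed
#' labels, and scores the result with [score_segmentation()]. The search
#' stops at the first alpha whose score is strictly worse than its
#' predecessor's, and the best-scoring state seen is returned.
#'
#' @param g a [NeighborGraph].
#' @param U n x K data penalty matrix.
#' @param S K x K interaction matrix.
#' @param observed_labels integer observed state labels (from
#'   [initial_labels()]); fixed across all alphas.
#' @param init initial labels for the expansion (defaults to
#'   `observed_labels`).
#' @param start,step,max_alpha search grid (defaults 10, 10, 100).
#' @param exclude_noise drop noise segments before taking the gene-level
#'   minimum p (default TRUE).
#' @param noise_max_size,noise_min_p the noise-segment rule: at most
#'   `noise_max_size` nodes AND p >= `noise_min_p` (defaults 9 and 0.1).
#' @param mode `"tail"` (default) or `"pmf"`, see [segment_pvalue()].
#' @param max_sweeps passed to [alpha_expansion()].
#' @return A list with `best_alpha`, `best_score`, `best_p`,
#'   `best_segmentation`, `best_labels`, and `trace` (a data frame with one
#'   row per evaluated alpha).
#' @export
search_smooth_factor <- function(g, U, S, observed_labels,
                                 init = observed_labels,
                                 start = 10, step = 10, max_alpha = 100,
                                 exclude_noise = TRUE,
                                 noise_max_size = 9L, noise_min_p = 0.1,
                                 mode = c("tail", "pmf"),
                                 max_sweeps = 10L) {
  mode <- match.arg(mode)
  stopifnot(start > 0, step > 0, max_alpha >= start)
  alphas <- seq(start, max_alpha, by = step)
  best <- NULL
  prev_score <- NULL
  trace <- data.frame(alpha = numeric(0), score = numeric(0),
                      best_p = numeric(0), n_segments = integer(0),
                      n_noise = integer(0))
  for (alpha in alphas) {
    lf <- alpha_expansion(g, U, S, alpha, init, max_sweeps = max_sweeps)
    seg <- extract_segments(g, lf$labels)
    gp <- gene_pvalue(seg, observed_labels, exclude_noise = exclude_noise,
                      noise_max_size = noise_max_size,
                      noise_min_p = noise_min_p, mode = mode)
    n_noise <- sum(gp$tests$noise)
    score <- score_segmentation(gp$best_p, n_noise, g$n)
    trace <- rbind(trace, data.frame(alpha = alpha, score = score,
                                     best_p = gp$best_p,
                                     n_segments = length(seg$segments),
                                     n_noise = n_noise))
    if (is.null(best) || score > best$best_score) {
      best <- list(best_alpha = alpha, best_score = score,
                   best_p = gp$best_p, best_segmentation = seg,
                   best_labels = lf$labels, tests = gp$tests)
    }
    if (!is.null(prev_score) && score < prev_score) break
    prev_score <- score
  }
  best$trace <- trace
  best
}
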