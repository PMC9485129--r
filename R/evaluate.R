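#' Confusion-matrix metrics for SV gene calls
#'
#' Computes accuracy `(TP + TN) / (TP + TN + FP + FN)`, sensitivity
#' `TP / (TP + FN)`, false positive rate `FP / (FP + TN)`, and F1
#' `2 TP / (2 TP + FN + FP)` from truth and call vectors. Metrics whose
#' denominator is zero are reported as 0 with `degenerate = TRUE`.
#'
#' @param truth,called logical vectors of equal length (TRUE = spatially
#'   variable).
#' @return A list with `TP`, `FP`, `TN`, `FN`, `accuracy`, `sensitivity`,
#'   `fpr`, `f1`, `degenerate`.
#' @export
confusion_metrics <- function(truth, called) {
  stopifnot(length(truth) == length(called))
  truth <- as.logical(truth); called <- as.logical(called)
  TP <- sum(truth & called); FP <- sum(!truth & called)
  TN <- sum(!truth & !called); FN <- sum(truth & !called)
  safe <- function(num, den) if (den == 0) 0 else num / den
  list(TP = TP, FP = FP, TN = TN, FN = FN,
       accuracy = safe(TP + TN, TP + TN + FP + FN),
       sensitivity = safe(TP, TP + FN),
       fpr = safe(FP, FP + TN),
       f1 = safe(2 * TP, 2 * TP + FN + FP),
       degenerate = (TP + FN) == 0 || (FP + TN) == 0)
}

on_polygon_boundary <- function(pts, poly, tol = 1e-9) {
  m <- nrow(poly)
  out <- rep(FALSE, nrow(pts))
  for (i in seq_len(m)) {
    a <- poly[i, ]; b <- poly[if (i == m) 1L else i + 1L, ]
    ab <- b - a
    len2 <- sum(ab^2)
    t <- if (len2 == 0) rep(0, nrow(pts)) else
      pmin(1, pmax(0, ((pts[, 1L] - a[1L]) * ab[1L] +
                         (pts[, 2L] - a[2L]) * ab[2L]) / len2))
    dx <- pts[, 1L] - (a[1L] + t * ab[1L])
    dy <- pts[, 2L] - (a[2L] + t * ab[2L])
    out <- out | (dx * dx + dy * dy <= tol^2)
  }
  out
}

#' Assign spots to annotated tissue layers
#'
#' Point-in-polygon assignment of spot coordinates to reference layer
#' boundaries. Each spot receives the first (in listed order) layer whose
#' polygon contains it; points exactly on a boundary count as contained.
#' Spots outside all layers are returned as `NA`.
#'
#' @param coords numeric n x 2 matrix of spot coordinates.
#' @param layers either a list of polygons (each a 2-column matrix or data
#'   frame of ring vertices) or an integer vector of per-spot layer labels
#'   (returned unchanged).
#' @return Integer layer index per spot, `NA` when unassigned.
#' @export
assign_points_to_layers <- function(coords, layers) {
  if (!is.list(layers)) {
    stopifnot(length(layers) == nrow(coords))
    return(as.integer(layers))
  }
  coords <- as.matrix(coords)
  out <- rep(NA_integer_, nrow(coords))
  for (li in seq_along(layers)) {
    poly <- as.matrix(layers[[li]])[, 1:2, drop = FALSE]
    inside <- mgcv::in.out(rbind(poly, poly[1L, ]), coords) |
      on_polygon_boundary(coords, poly)
    out[is.na(out) & inside] <- li
  }
  out
}

#' Match segments to reference layers by maximum overlap
#'
#' Each segment bit-vector `v` is assigned to the reference layer `u` with
#' the largest overlap `|v AND u|`; ties (including the degenerate case of
#' zero overlap with every layer) resolve to the lowest layer index, with
#' the zero-overlap case flagged.
#'
#' @param seg_vectors list of logical/0-1 vectors, one per segment.
#' @param ref_vectors list of logical/0-1 vectors, one per layer.
#' @return A data frame with columns `segment`, `layer`, `overlap`,
#'   `no_overlap`.
#' @export
match_segments_to_layers <- function(seg_vectors, ref_vectors) {
  res <- lapply(seq_along(seg_vectors), function(i) {
    v <- as.logical(seg_vectors[[i]])
    ov <- vapply(ref_vectors, function(u) sum(v & as.logical(u)), numeric(1))
    data.frame(segment = i, layer = which.max(ov), overlap = max(ov),
               no_overlap = max(ov) == 0)
  })
  do.call(rbind, res)
}

#' Normalized Hamming distance between bit vectors
#'
#' `|XOR(u, v)| / (|AND(u, v)| + a)`: the number of disagreeing positions
#' relative to the (regularized) overlap. The constant `a` (default 10)
#' guards against division by zero for disjoint supports.
#'
#' @param u,v logical/0-1 vectors of equal length.
#' @param a positive regularization constant (default 10).
#' @return The distance (0 iff the supports are identical).
#' @export
normalized_hamming <- function(u, v, a = 10) {
  u <- as.logical(u); v <- as.logical(v)
  stopifnot(length(u) == length(v), a > 0)
  sum(xor(u, v)) / (sum(u & v) + a)
}

#' Jaccard and Hausdorff distances between spatial supports
#'
#' Jaccard distance `1 - |u AND v| / |u OR v|` (1 if the union is empty) and
#' the symmetric Hausdorff distance between the coordinate sets selected by
#' `u` and `v`. When either coordinate set is empty the Hausdorff distance
#' is undefined; the diameter of the full coordinate set is returned as a
#' sentinel with `hausdorff_degenerate = TRUE`.
#'
#' @param u,v logical/0-1 vectors of equal length.
#' @param coords numeric n x 2 coordinate matrix.
#' @return A list with `jaccard`, `hausdorff`, `hausdorff_degenerate`.
#' @export
structure_distances <- function(u, v, coords) {
  u <- as.logical(u); v <- as.logical(v)
  coords <- as.matrix(coords)
  stopifnot(length(u) == length(v), length(u) == nrow(coords))
  uni <- sum(u | v)
  jac <- if (uni == 0) 1 else 1 - sum(u & v) / uni
  if (!any(u) || !any(v)) {
    d <- as.matrix(stats::dist(coords))
    return(list(jaccard = jac, hausdorff = max(d),
                hausdorff_degenerate = TRUE))
  }
  hd <- pracma::hausdorff_dist(coords[u, , drop = FALSE],
                               coords[v, , drop = FALSE])
  list(jaccard = jac, hausdorff = hd, hausdorff_degenerate = FALSE)
}

#' Overlap-matched labeling accuracy
#'
#' Maps each predicted cluster to the true class it overlaps most (several
#' clusters may map to the same class), then reports the fraction of spots
#' whose mapped label matches the truth. With `optimal = TRUE` a one-to-one
#' assignment maximizing total overlap is used instead (exhaustive over
#' permutations; intended for small numbers of clusters).
#'
#' @param pred,truth integer label vectors of equal length.
#' @param optimal use optimal one-to-one matching (default FALSE).
#' @return Accuracy in `[0, 1]`.
#' @export
overlap_accuracy <- function(pred, truth, optimal = FALSE) {
  stopifnot(length(pred) == length(truth))
  pu <- sort(unique(pred)); tu <- sort(unique(truth))
  ov <- outer(pu, tu, Vectorize(function(p, t) sum(pred == p & truth == t)))
  if (!optimal) {
    map <- tu[max.col(ov, ties.method = "first")]
    return(mean(map[match(pred, pu)] == truth))
  }
  k <- length(pu)
  if (length(tu) < k) stop("optimal matching needs at least as many classes")
  perms <- all_permutations(seq_along(tu), k)
  best <- 0
  for (i in seq_len(nrow(perms))) {
    tot <- sum(ov[cbind(seq_len(k), perms[i, ])])
    best <- max(best, tot)
  }
  best / length(pred)
}

all_permutations <- function(v, k) {
  if (k == 1L) return(matrix(v, ncol = 1L))
  out <- NULL
  for (i in seq_along(v)) {
    rest <- all_permutations(v[-i], k - 1L)
    out <- rbind(out, cbind(v[i], rest))
  }
  out
}

#' Reconstruct tissue structure from SV genes
#'
#' Rebuilds spatial domains from a set of SV genes: spots are clustered by
#' seeded k-means on their SV-gene expression profiles, the cluster
#' assignment initializes a Markov random field whose data penalty is the
#' Euclidean distance of each spot's profile to each centroid, and the
#' labels are refined by [alpha_expansion()]. Cluster labels are nominal,
#' so the default interaction is the Potts penalty (a constant cost for any
#' label disagreement); set `potts = FALSE` for the ordinal penalty.
#'
#' @param x a [SpatialExpression] (normalized, log-transformed).
#' @param sv_genes character vector of gene ids to use.
#' @param g a [NeighborGraph] over the spots of `x`.
#' @param k number of layers/clusters (>= 1).
#' @param alpha smooth factor; 0 returns the plain k-means assignment. The
#'   default 1 is deliberately below the centroid-separation scale: data
#'   penalties here are Euclidean distances in gene space (order sqrt(g)
#'   for g genes), so smoothing is a speckle-removing refinement of the
#'   clustering, not a force that can overwhelm it.
#' @param seed integer seed for k-means.
#' @param potts use the Potts interaction (default TRUE).
#' @param penalty_factor interaction magnitude (default 1).
#' @return Integer layer labels in `1..k`, one per spot.
#' @export
reconstruct_tissue <- function(x, sv_genes, g, k, alpha = 1, seed = 1L,
                               potts = TRUE, penalty_factor = 1) {
  stopifnot(inherits(x, "SpatialExpression"), inherits(g, "NeighborGraph"),
            k >= 1L)
  missing_genes <- setdiff(sv_genes, x$gene_ids)
  if (length(missing_genes))
    stop("genes not present: ", paste(utils::head(missing_genes, 5L),
                                      collapse = ", "))
  X <- x$counts[, sv_genes, drop = FALSE]
  if (k == 1L) return(rep(1L, nrow(X)))
  set.seed(as.integer(seed))
  km <- stats::kmeans(X, centers = k, nstart = 10L, iter.max = 100L)
  U <- vapply(seq_len(k), function(j)
    sqrt(rowSums(sweep(X, 2L, km$centers[j, ])^2)), numeric(nrow(X)))
  if (alpha == 0) return(as.integer(km$cluster))
  S <- if (potts) {
    m <- matrix(penalty_factor, k, k); diag(m) <- 0; m
  } else {
    interaction_matrix(k, penalty_factor)
  }
  lf <- alpha_expansion(g, U, S, alpha, init = as.integer(km$cluster))
  lf$labels
}
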