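#' Build the Delaunay neighbor graph
#'
#' Converts 2-D spot/cell coordinates into the undirected neighbor graph of
#' the hidden Markov random field. Delaunay triangulation connects only
#' authentic neighbors (no third point lies inside the circumcircle of a
#' triangle), giving a sparse, planar graph: at most `3n - 6` edges.
#'
#' The dual Voronoi tessellation is computed at the same time and cached on
#' the graph for boundary highlighting ([voronoi_boundaries()]) and plotting;
#' infinite Voronoi ridges of hull cells are clipped to the coordinate
#' bounding box expanded by 5% (visualization only, never statistics).
#'
#' @param coords numeric n x 2 matrix of planar coordinates, n >= 3, not all
#'   collinear, no duplicates.
#' @return An object of class `NeighborGraph`: list with `n`, `edges` (m x 2
#'   integer matrix, each row an unordered pair with `i < j`), `adjacency`
#'   (list of neighbor index vectors), `coords`, and `voronoi` (data frame of
#'   ridge segments with the Delaunay edge each ridge is dual to).
#' @export
build_delaunay_graph <- function(coords) {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  n <- nrow(coords)
  if (n < 3L) stop("at least 3 points are required")
  if (anyDuplicated(coords)) stop("duplicate coordinates; triangulation undefined")
  ctr <- sweep(coords, 2L, colMeans(coords))
  if (qr(ctr)$rank < 2L)
    stop("points are collinear; Delaunay triangulation is degenerate")
  rng_x <- range(coords[, 1L]); rng_y <- range(coords[, 2L])
  pad_x <- max(diff(rng_x), .Machine$double.eps) * 0.05
  pad_y <- max(diff(rng_y), .Machine$double.eps) * 0.05
  dd <- deldir::deldir(coords[, 1L], coords[, 2L],
                       rw = c(rng_x[1L] - pad_x, rng_x[2L] + pad_x,
                              rng_y[1L] - pad_y, rng_y[2L] + pad_y),
                       suppressMsge = TRUE)
  e <- cbind(pmin(dd$delsgs$ind1, dd$delsgs$ind2),
             pmax(dd$delsgs$ind1, dd$delsgs$ind2))
  e <- e[order(e[, 1L], e[, 2L]), , drop = FALSE]
  e <- unique(e)
  storage.mode(e) <- "integer"
  g <- structure(
    list(n = n, edges = e, adjacency = edges_to_adjacency(e, n),
         coords = coords, voronoi = dd$dirsgs),
    class = "NeighborGraph"
  )
  comp <- graph_components(g)
  if (max(comp) > 1L)
    warning("neighbor graph is disconnected: ", max(comp), " components (",
            paste(tabulate(comp), collapse = ", "), " nodes)")
  g
}

edges_to_adjacency <- function(edges, n) {
  adj <- vector("list", n)
  for (i in seq_len(n)) adj[[i]] <- integer(0)
  if (nrow(edges)) {
    nb <- split(c(edges[, 2L], edges[, 1L]),
                factor(c(edges[, 1L], edges[, 2L]), levels = seq_len(n)))
    adj <- lapply(nb, function(v) sort(unique(v)))
  }
  adj
}

graph_components <- function(g, edges = g$edges) {
  ig <- igraph::make_empty_graph(n = g$n, directed = FALSE)
  if (nrow(edges)) ig <- igraph::add_edges(ig, t(edges))
  igraph::components(ig)$membership
}

#' @exportS3Method print NeighborGraph
print.NeighborGraph <- function(x, ...) {
  cat("NeighborGraph: ", x$n, " nodes, ", nrow(x$edges), " edges\n", sep = "")
  invisible(x)
}

edge_lengths <- function(g) {
  d <- g$coords[g$edges[, 1L], , drop = FALSE] -
       g$coords[g$edges[, 2L], , drop = FALSE]
  sqrt(rowSums(d^2))
}

#' Prune unusually long edges
#'
#' Removes Delaunay edges longer than the given percentile of all edge
#' lengths -- typically spurious convex-hull spans across concave tissue --
#' while never disconnecting the graph: an edge whose removal would split a
#' component is retained. Default `percentile = 100` is the identity; the
#' triangulation is used as-is unless pruning is requested.
#'
#' @param g a [NeighborGraph].
#' @param percentile in (0, 100]; edges strictly longer than this percentile
#'   of the edge-length distribution are candidates for removal.
#' @return A pruned `NeighborGraph`.
#' @export
prune_long_edges <- function(g, percentile = 100) {
  stopifnot(inherits(g, "NeighborGraph"), percentile > 0, percentile <= 100)
  len <- edge_lengths(g)
  thr <- stats::quantile(len, percentile / 100, names = FALSE)
  cand <- which(len > thr)
  if (!length(cand)) return(g)
  edges <- g$edges
  keep <- rep(TRUE, nrow(edges))
  # longest first, so the worst offenders go unless they are bridges
  for (i in cand[order(len[cand], decreasing = TRUE)]) {
    keep[i] <- FALSE
    comp <- graph_components(g, edges[keep, , drop = FALSE])
    if (max(comp) > 1L) keep[i] <- TRUE
  }
  g$edges <- edges[keep, , drop = FALSE]
  g$adjacency <- edges_to_adjacency(g$edges, g$n)
  g
}

#' Voronoi boundary segments between label domains
#'
#' Returns the Voronoi ridge segments dual to Delaunay edges whose two
#' endpoints carry different labels -- the drawn boundary of the label
#' domains. A uniform labeling yields an empty set.
#'
#' @param g a [NeighborGraph] built by [build_delaunay_graph()].
#' @param labels integer vector of length `g$n`.
#' @return A data frame with columns `x1, y1, x2, y2` (ridge endpoints),
#'   `ind1, ind2` (the dual Delaunay edge) and `clipped` (TRUE if the ridge
#'   was an infinite hull ridge clipped to the drawing window).
#' @export
voronoi_boundaries <- function(g, labels) {
  stopifnot(inherits(g, "NeighborGraph"), length(labels) == g$n)
  vor <- g$voronoi
  if (is.null(vor)) stop("graph carries no cached Voronoi tessellation")
  disc <- labels[vor$ind1] != labels[vor$ind2]
  # restrict to ridges dual to edges still present in the (possibly pruned)
  # graph, and drop degenerate zero-length ridges (cocircular point sets)
  key <- paste(pmin(vor$ind1, vor$ind2), pmax(vor$ind1, vor$ind2))
  present <- key %in% paste(g$edges[, 1L], g$edges[, 2L])
  finite_ridge <- (vor$x1 - vor$x2)^2 + (vor$y1 - vor$y2)^2 > 0
  sel <- disc & present & finite_ridge
  out <- vor[sel, c("x1", "y1", "x2", "y2", "ind1", "ind2")]
  out$clipped <- vor$bp1[sel] | vor$bp2[sel]
  rownames(out) <- NULL
  out
}
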