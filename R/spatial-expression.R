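#' Spatial expression container
#'
#' Bundles a spot/cell coordinate table with an expression matrix. This is
#' the universal input object of the package: every downstream step (graph
#' construction, state calling, segmentation, testing) consumes it.
#'
#' @param coords numeric matrix with n rows and 2 columns (x, y), arbitrary
#'   planar units.
#' @param counts numeric matrix with n rows (spots) and g columns (genes),
#'   non-negative. Raw counts or normalized values.
#' @param spot_ids character vector of n unique spot identifiers.
#' @param gene_ids character vector of g unique gene identifiers.
#' @param normalized logical flag; `TRUE` once library-size normalization has
#'   been applied.
#'
#' @return An object of class `SpatialExpression`: a list with elements
#'   `coords`, `counts`, `spot_ids`, `gene_ids`, `normalized`.
#'
#' @details Duplicate coordinates are rejected outright (with the offending
#'   spot ids named) rather than jittered: the Delaunay triangulation used
#'   downstream requires points in general position, and silent jitter would
#'   corrupt the geometry it is meant to fix.
#'
#' @export
SpatialExpression <- function(coords, counts, spot_ids = NULL, gene_ids = NULL,
                              normalized = FALSE) {
  coords <- as.matrix(coords)
  counts <- as.matrix(counts)
  storage.mode(coords) <- "double"
  storage.mode(counts) <- "double"
  n <- nrow(coords)
  if (ncol(coords) != 2L)
    stop("'coords' must have exactly 2 columns (x, y)")
  if (nrow(counts) != n)
    stop("'counts' must have one row per spot (", n, " expected, got ",
         nrow(counts), ")")
  if (n < 3L)
    stop("at least 3 spots are required (got ", n, ")")
  if (is.null(spot_ids)) spot_ids <- rownames(counts)
  if (is.null(spot_ids)) spot_ids <- paste0("spot", seq_len(n))
  if (is.null(gene_ids)) gene_ids <- colnames(counts)
  if (is.null(gene_ids)) gene_ids <- paste0("gene", seq_len(ncol(counts)))
  spot_ids <- as.character(spot_ids)
  gene_ids <- as.character(gene_ids)
  if (anyDuplicated(spot_ids))
    stop("duplicate spot ids: ",
         paste(unique(spot_ids[duplicated(spot_ids)]), collapse = ", "))
  if (anyDuplicated(gene_ids))
    stop("duplicate gene ids: ",
         paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "))
  dup <- duplicated(coords)
  if (any(dup)) {
    stop("duplicate coordinates for spots: ",
         paste(spot_ids[dup], collapse = ", "),
         " (resolve duplicates before loading; jitter is not applied)")
  }
  if (any(counts < 0))
    stop("'counts' must be non-negative")
  dimnames(coords) <- list(spot_ids, c("x", "y"))
  dimnames(counts) <- list(spot_ids, gene_ids)
  structure(
    list(coords = coords, counts = counts, spot_ids = spot_ids,
         gene_ids = gene_ids, normalized = isTRUE(normalized)),
    class = "SpatialExpression"
  )
}

#' @exportS3Method print SpatialExpression
print.SpatialExpression <- function(x, ...) {
  cat("SpatialExpression: ", nrow(x$counts), " spots x ", ncol(x$counts),
      " genes (", if (x$normalized) "normalized" else "raw", ")\n", sep = "")
  invisible(x)
}

#' @export
dim.SpatialExpression <- function(x) dim(x$counts)

parse_coord_labels <- function(ids) {
  m <- regmatches(ids, regexec("^\\s*(-?[0-9]*\\.?[0-9]+)[x×](-?[0-9]*\\.?[0-9]+)\\s*$",
                               ids))
  bad <- vapply(m, length, 1L) != 3L
  if (any(bad))
    stop("cannot parse coordinates from row label(s): ",
         paste(utils::head(ids[bad], 5L), collapse = ", "))
  cbind(x = as.numeric(vapply(m, `[`, "", 2L)),
        y = as.numeric(vapply(m, `[`, "", 3L)))
}

#' Read spatial expression data
#'
#' Reads a spots-by-genes table (TSV/CSV) or a MatrixMarket triplet file with
#' sidecar gene and spot lists. For tabular input the first column holds spot
#' ids; coordinates come either from explicit `x`/`y` columns or from
#' `"x<sep>y"`-encoded row labels (separator `x` or the times sign). For MTX
#' input the matrix is genes-in-rows (the common convention) and is
#' transposed to spots-by-genes on load; `spots_file` is either a one-column
#' list of coordinate-encoded ids or a table with columns id, x, y.
#'
#' Genes with all-zero counts are retained; filtering is an explicit step
#' ([filter_genes()]).
#'
#' @param path path to the expression table or `.mtx` file.
#' @param fmt one of `"tsv"`, `"csv"`, `"mtx"`.
#' @param genes_file,spots_file sidecar files, required for `fmt = "mtx"`.
#' @return A [SpatialExpression] object with raw counts.
#' @export
read_spatial_expression <- function(path, fmt = c("tsv", "csv", "mtx"),
                                    genes_file = NULL, spots_file = NULL) {
  fmt <- match.arg(fmt)
  if (!file.exists(path)) stop("file not found: ", path)
  if (fmt == "mtx") {
    if (is.null(genes_file) || is.null(spots_file))
      stop("'genes_file' and 'spots_file' are required for fmt = 'mtx'")
    m <- as.matrix(Matrix::readMM(path))      # genes x spots
    genes <- readLines(genes_file)
    spot_tab <- utils::read.table(spots_file, header = FALSE,
                                  stringsAsFactors = FALSE)
    if (ncol(spot_tab) >= 3L) {
      spot_ids <- as.character(spot_tab[[1L]])
      coords <- cbind(x = as.numeric(spot_tab[[2L]]),
                      y = as.numeric(spot_tab[[3L]]))
    } else {
      spot_ids <- as.character(spot_tab[[1L]])
      coords <- parse_coord_labels(spot_ids)
    }
    if (nrow(m) != length(genes))
      stop("gene list length (", length(genes),
           ") does not match matrix rows (", nrow(m), ")")
    if (ncol(m) != length(spot_ids))
      stop("spot list length (", length(spot_ids),
           ") does not match matrix columns (", ncol(m), ")")
    return(SpatialExpression(coords, t(m), spot_ids, genes))
  }
  sep <- if (fmt == "tsv") "\t" else ","
  tab <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                           stringsAsFactors = FALSE, row.names = NULL)
  spot_ids <- as.character(tab[[1L]])
  tab <- tab[, -1L, drop = FALSE]
  nm <- names(tab)
  if (all(c("x", "y") %in% nm)) {
    coords <- cbind(x = as.numeric(tab[["x"]]), y = as.numeric(tab[["y"]]))
    tab <- tab[, setdiff(nm, c("x", "y")), drop = FALSE]
  } else {
    coords <- parse_coord_labels(spot_ids)
  }
  counts <- as.matrix(tab)
  SpatialExpression(coords, counts, spot_ids, colnames(counts))
}

#' Write spatial expression data
#'
#' Inverse of [read_spatial_expression()]: a round trip through write and
#' read reproduces the object.
#'
#' @param x a [SpatialExpression] object.
#' @param path output path (`.mtx` file for `fmt = "mtx"`).
#' @param fmt one of `"tsv"`, `"csv"`, `"mtx"`.
#' @param genes_file,spots_file sidecar paths for `fmt = "mtx"`.
#' @return `path`, invisibly.
#' @export
write_spatial_expression <- function(x, path, fmt = c("tsv", "csv", "mtx"),
                                     genes_file = NULL, spots_file = NULL) {
  stopifnot(inherits(x, "SpatialExpression"))
  fmt <- match.arg(fmt)
  if (fmt == "mtx") {
    if (is.null(genes_file) || is.null(spots_file))
      stop("'genes_file' and 'spots_file' are required for fmt = 'mtx'")
    Matrix::writeMM(Matrix::Matrix(t(x$counts), sparse = TRUE), path)
    writeLines(x$gene_ids, genes_file)
    utils::write.table(
      data.frame(id = x$spot_ids, x = x$coords[, 1L], y = x$coords[, 2L]),
      spots_file, sep = "\t", quote = FALSE, row.names = FALSE,
      col.names = FALSE)
    return(invisible(path))
  }
  sep <- if (fmt == "tsv") "\t" else ","
  out <- data.frame(spot = x$spot_ids, x = x$coords[, 1L], y = x$coords[, 2L],
                    x$counts, check.names = FALSE)
  utils::write.table(out, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Median-of-totals count normalization
#'
#' Scales each spot's counts by (median of per-spot totals) / (that spot's
#' total), the library-size normalization used by the Cell Ranger pipeline.
#' Spots with zero total are left at zero. Within-spot proportions between
#' genes are unchanged.
#'
#' @param x a [SpatialExpression] object with raw counts.
#' @return A [SpatialExpression] with normalized counts and `normalized = TRUE`.
#' @export
normalize_counts <- function(x) {
  stopifnot(inherits(x, "SpatialExpression"))
  if (x$normalized) {
    warning("counts are already normalized; returning input unchanged")
    return(x)
  }
  totals <- rowSums(x$counts)
  med <- stats::median(totals)
  scale <- ifelse(totals > 0, med / totals, 0)
  x$counts <- x$counts * scale
  x$normalized <- TRUE
  x
}

#' Log2 transform with pseudocount
#'
#' @param x a [SpatialExpression] object.
#' @param pseudocount positive offset added before taking log2 (default 1;
#'   zeros are ubiquitous in count data).
#' @return A [SpatialExpression] with `log2(counts + pseudocount)`.
#' @export
log_transform <- function(x, pseudocount = 1) {
  stopifnot(inherits(x, "SpatialExpression"))
  if (pseudocount <= 0) stop("'pseudocount' must be > 0")
  if (any(x$counts < 0)) stop("negative entries; log transform undefined")
  x$counts <- log2(x$counts + pseudocount)
  x
}

#' Filter genes by detection
#'
#' Keeps genes with nonzero expression in at least `min_spots` spots,
#' preserving gene order. The default of 10 matches the segment-size scale at
#' which the smooth-factor score already treats segments as noise: a gene
#' detected in fewer than 10 spots cannot support a non-noise segment.
#'
#' @param x a [SpatialExpression] object.
#' @param min_spots minimum number of spots with nonzero expression.
#' @return A filtered [SpatialExpression].
#' @export
filter_genes <- function(x, min_spots = 10) {
  stopifnot(inherits(x, "SpatialExpression"), min_spots >= 0)
  keep <- colSums(x$counts > 0) >= min_spots
  if (!any(keep))
    stop("no genes pass the filter (min_spots = ", min_spots, ")")
  x$counts <- x$counts[, keep, drop = FALSE]
  x$gene_ids <- x$gene_ids[keep]
  x
}

#' Write a gene result table
#'
#' @param results a data frame with columns `gene`, `p_value`, `q_value`,
#'   `smooth_factor`, `n_segments` (as produced by [run_pipeline()]).
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path) {
  if (inherits(results, "sv_results")) results <- results$table
  need <- c("gene", "p_value", "q_value", "smooth_factor", "n_segments")
  if (!all(need %in% names(results)))
    stop("results must contain columns: ", paste(need, collapse = ", "))
  utils::write.table(results[, need], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
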