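#' Deterministic sub-seed derivation
#'
#' Derives a reproducible per-task seed from a global seed and an index, so
#' results are identical regardless of evaluation order or worker count.
#' Values stay within the positive 32-bit integer range.
#'
#' @param seed global integer seed.
#' @param index non-negative task index.
#' @return An integer seed.
#' @export
derive_seed <- function(seed, index) {
  as.integer((as.double(seed) * 69069 + as.double(index) * 1234567 + 1) %%
               2147483647)
}

#' Synthetic three-region spot layout
#'
#' Emulates the geometry of a spatial transcriptomics slide: a jittered
#' square grid of `n` spots partitioned into three contiguous horizontal
#' bands with the requested fractions (sizes exact up to rounding). Bands
#' follow grid rows, so each region is connected in the Delaunay graph.
#' Defaults mirror a ~260-spot array split into three tissue layers.
#'
#' @param n number of spots (>= 30).
#' @param region_fractions three non-negative reals summing to 1.
#' @param seed integer seed (jitter only; the same seed reproduces the
#'   layout exactly).
#' @param jitter uniform jitter half-width in grid units (default 0.15).
#' @return A list with `coords` (n x 2 matrix, columns x, y) and `regions`
#'   (integer vector in 1..3).
#' @export
synthetic_layout <- function(n = 262L, region_fractions = c(0.4, 0.3, 0.3),
                             seed = 1L, jitter = 0.15) {
  stopifnot(n >= 30L, length(region_fractions) == 3L,
            all(region_fractions >= 0))
  if (abs(sum(region_fractions) - 1) > 1e-9)
    stop("'region_fractions' must sum to 1")
  nx <- ceiling(sqrt(n))
  ny <- ceiling(n / nx)
  gx <- rep(seq_len(nx), times = ny)[seq_len(n)]
  gy <- rep(seq_len(ny), each = nx)[seq_len(n)]
  set.seed(as.integer(seed))
  coords <- cbind(x = gx + stats::runif(n, -jitter, jitter),
                  y = gy + stats::runif(n, -jitter, jitter))
  n1 <- round(n * region_fractions[1L])
  n2 <- round(n * region_fractions[2L])
  n3 <- n - n1 - n2
  ord <- order(gy, gx)
  regions <- integer(n)
  regions[ord] <- rep.int(1:3, c(n1, n2, n3))
  list(coords = coords, regions = regions)
}

#' Simulate one spatially variable gene
#'
#' Draws each spot's expression from a region-specific normal distribution:
#' spots in regions 1, 2, 3 draw from `N(region_means[r], sigma^2)`
#' (defaults `N(0, s2)`, `N(1, s2)`, `N(2, s2)`). Larger `sigma` blurs the
#' between-region signal and degrades downstream sensitivity.
#'
#' @param regions integer region ids in 1..3 per spot.
#' @param sigma positive standard deviation.
#' @param region_means three region means (default `c(0, 1, 2)`).
#' @param seed integer seed.
#' @return Numeric expression vector, one value per spot.
#' @export
simulate_sv_gene <- function(regions, sigma, region_means = c(0, 1, 2),
                             seed = 1L) {
  stopifnot(sigma > 0, all(regions %in% seq_along(region_means)))
  set.seed(as.integer(seed))
  stats::rnorm(length(regions), mean = region_means[regions], sd = sigma)
}

#' Shuffle a gene's values across spots
#'
#' Produces a spatially random null gene: a uniformly random permutation of
#' the input values over the fixed spot positions. The value multiset is
#' preserved exactly.
#'
#' @param values numeric vector.
#' @param seed integer seed.
#' @return Permuted values.
#' @export
shuffle_gene <- function(values, seed = 1L) {
  if (length(values) <= 1L) return(values)
  set.seed(as.integer(seed))
  values[sample.int(length(values))]
}

#' Perturb expression values
#'
#' Two perturbation models for robustness studies: `"gaussian_noise"` adds
#' i.i.d. `N(0, amount^2)` noise to every spot; `"exchange"` selects
#' `floor(amount * n)` spots and cyclically permutes their values among
#' themselves (a derangement: every selected spot receives another selected
#' spot's value), leaving all other spots untouched.
#'
#' @param values numeric vector.
#' @param mode `"gaussian_noise"` or `"exchange"`.
#' @param amount noise standard deviation (>= 0), or exchanged fraction in
#'   `[0, 1]`.
#' @param seed integer seed.
#' @return Perturbed values.
#' @export
perturb <- function(values, mode = c("gaussian_noise", "exchange"),
                    amount, seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(amount >= 0)
  if (amount == 0) return(values)
  set.seed(as.integer(seed))
  if (mode == "gaussian_noise")
    return(values + stats::rnorm(length(values), 0, amount))
  stopifnot(amount <= 1)
  m <- floor(amount * length(values))
  if (m < 2L) return(values)
  sel <- sample.int(length(values), m)
  ord <- sample.int(m)
  cyc <- sel[ord]
  values[cyc] <- values[c(cyc[-1L], cyc[1L])]
  values
}

#' Transform simulated expression values to counts
#'
#' Inverts the median-of-totals normalization plus log2 transform used by
#' the analysis pipeline: each spot's values are exponentiated base 2,
#' converted to within-spot shares, allocated proportionally to the spot's
#' sequencing depth, and rounded stochastically (floor plus a Bernoulli on
#' the fractional part), so each spot's total matches its depth up to
#' per-gene rounding. Applying [normalize_counts()] and [log_transform()]
#' to the output recovers the input values up to an affine transform.
#'
#' @param values numeric n x g matrix (spots x genes) of expression values
#'   on a log2-like scale.
#' @param depth_profile length-n positive vector of per-spot library sizes.
#' @param seed integer seed for the stochastic rounding.
#' @return Non-negative integer n x g matrix.
#' @export
to_counts <- function(values, depth_profile, seed = 1L) {
  values <- as.matrix(values)
  n <- nrow(values)
  stopifnot(length(depth_profile) == n, all(depth_profile > 0))
  w <- 2^values
  target <- (w / rowSums(w)) * depth_profile
  set.seed(as.integer(seed))
  lo <- floor(target)
  frac <- target - lo
  counts <- lo + (matrix(stats::runif(length(target)), n) < frac)
  storage.mode(counts) <- "integer"
  dimnames(counts) <- dimnames(values)
  counts
}

#' Generate the simulation benchmark
#'
#' Builds a complete labeled benchmark with no external data: a three-region
#' layout ([synthetic_layout()]), `n_sv` spatially variable genes drawn from
#' region-mean normals at the given `sigma`, and `n_null` null genes formed
#' by shuffling SV genes across spots (after any perturbation, so nulls and
#' SV genes share their value distribution exactly). Values are then
#' converted to counts against a log-normal depth profile, yielding raw
#' input for the full pipeline.
#'
#' @param n_sv,n_null numbers of spatially variable and shuffled null genes
#'   (defaults 1000 and 9000, the genome-scale profile; use e.g. 100/900
#'   for quick runs).
#' @param sigma region-normal standard deviation (0.1 = strong signal,
#'   0.6 = weak).
#' @param n_spots,region_fractions,region_means layout and signal
#'   parameters, see [synthetic_layout()] and [simulate_sv_gene()].
#' @param noise_sd,exchange_frac optional perturbations applied to the SV
#'   genes before shuffling, see [perturb()].
#' @param depth_profile per-spot library sizes; default log-normal with
#'   median 10000 reads.
#' @param counts if `TRUE` (default) emit count data; if `FALSE` keep the
#'   simulated values directly (flagged as normalized, for running the
#'   pipeline without the count layer).
#' @param layout optional list with elements `coords` (n x 2 matrix) and
#'   `regions` (integer vector) replacing the synthetic layout -- the hook
#'   for real slide coordinates or for the parametric patterns of
#'   [pattern_regions()]. `region_means` must then have one entry per
#'   region id.
#' @param seed global integer seed; all sub-seeds derive from it.
#' @return An object of class `sv_benchmark`: list with `matrix` (a
#'   [SpatialExpression]), `truth` (logical SV flag per gene), `regions`,
#'   `sigma`, `params`.
#' @export
make_benchmark <- function(n_sv = 1000L, n_null = 9000L, sigma = 0.3,
                           n_spots = 262L,
                           region_fractions = c(0.4, 0.3, 0.3),
                           region_means = c(0, 1, 2),
                           noise_sd = 0, exchange_frac = 0,
                           depth_profile = NULL, counts = TRUE,
                           layout = NULL, seed = 1L) {
  stopifnot(n_sv >= 1L, n_null >= 0L)
  lay <- if (is.null(layout)) {
    synthetic_layout(n_spots, region_fractions, seed = derive_seed(seed, 0L))
  } else {
    stopifnot(is.list(layout), nrow(layout$coords) == length(layout$regions))
    layout
  }
  n <- nrow(lay$coords)
  n_spots <- n
  g <- n_sv + n_null
  vals <- matrix(0, n, g)
  for (j in seq_len(n_sv)) {
    v <- simulate_sv_gene(lay$regions, sigma, region_means,
                          seed = derive_seed(seed, j))
    if (noise_sd > 0)
      v <- perturb(v, "gaussian_noise", noise_sd,
                   seed = derive_seed(seed, g + j))
    if (exchange_frac > 0)
      v <- perturb(v, "exchange", exchange_frac,
                   seed = derive_seed(seed, 2L * g + j))
    vals[, j] <- v
  }
  for (j in seq_len(n_null)) {
    src <- ((j - 1L) %% n_sv) + 1L
    vals[, n_sv + j] <- shuffle_gene(vals[, src],
                                     seed = derive_seed(seed, 3L * g + j))
  }
  gene_ids <- c(sprintf("SV%04d", seq_len(n_sv)),
                if (n_null) sprintf("NULL%04d", seq_len(n_null)))
  spot_ids <- sprintf("s%03d", seq_len(n))
  dimnames(vals) <- list(spot_ids, gene_ids)
  if (counts) {
    if (is.null(depth_profile)) {
      set.seed(derive_seed(seed, 4L * g + 1L))
      depth_profile <- round(stats::rlnorm(n, log(1e4), 0.25))
    }
    mat <- SpatialExpression(lay$coords,
                             to_counts(vals, depth_profile,
                                       seed = derive_seed(seed, 4L * g + 2L)),
                             spot_ids, gene_ids, normalized = FALSE)
  } else {
    mat <- SpatialExpression(lay$coords, vals - min(vals), spot_ids, gene_ids,
                             normalized = TRUE)
  }
  structure(
    list(matrix = mat, truth = c(rep(TRUE, n_sv), rep(FALSE, n_null)),
         regions = lay$regions, sigma = sigma,
         params = list(n_sv = n_sv, n_null = n_null, sigma = sigma,
                       n_spots = n_spots,
                       region_fractions = region_fractions,
                       region_means = region_means, noise_sd = noise_sd,
                       exchange_frac = exchange_frac, counts = counts,
                       seed = seed)),
    class = "sv_benchmark"
  )
}
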