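#' Fit a one-dimensional Gaussian mixture by EM
#'
#' Models a gene's log2 expression values as a K-component Gaussian mixture
#' `p(x) = sum_k pi_k N(x | mu_k, sigma2_k)` fitted by expectation-
#' maximization. Components are relabeled so that means ascend: state labels
#' then follow expression level, and adjacent cells with larger expression
#' differences receive larger state differences (which the ordinal
#' interaction energy turns into larger smoothing penalties).
#'
#' EM is initialized from a seeded k-means partition, runs to a log-
#' likelihood tolerance of `tol` (default 1e-4) or `max_iter` iterations,
#' and floors component variances at `1e-6 * var(values)` to stop components
#' collapsing onto single points (a warning is issued when the floor binds).
#'
#' @param values numeric vector of observations (length n > K).
#' @param K number of mixture components (>= 1).
#' @param seed integer seed for the k-means initialization.
#' @param tol convergence tolerance on the log-likelihood.
#' @param max_iter maximum EM iterations.
#' @return An object of class `GeneGMM`: list with `K`, `weights`, `means`
#'   (ascending), `variances`, `loglik`, `bic`, `n`. BIC is
#'   `-2 loglik + (3K - 1) log(n)` (K means, K variances, K - 1 free
#'   weights).
#' @export
fit_gmm <- function(values, K, seed = 1L, tol = 1e-4, max_iter = 200L) {
  values <- as.numeric(values)
  n <- length(values)
  if (K < 1L) stop("'K' must be >= 1")
  if (n <= K) stop("need more observations (", n, ") than components (", K, ")")
  vfloor <- max(1e-6 * stats::var(values), 1e-12)

  if (K == 1L) {
    mu <- mean(values)
    v <- max(stats::var(values) * (n - 1) / n, vfloor)
    ll <- sum(stats::dnorm(values, mu, sqrt(v), log = TRUE))
    return(new_gmm(1L, 1, mu, v, ll, n))
  }

  set.seed(as.integer(seed))
  km <- tryCatch(
    stats::kmeans(values, centers = K, nstart = 5L, iter.max = 50L),
    error = function(e) NULL)
  if (is.null(km)) {
    mu <- stats::quantile(values, probs = (seq_len(K) - 0.5) / K, names = FALSE)
    assign0 <- max.col(-abs(outer(values, mu, "-")), ties.method = "first")
  } else {
    mu <- as.numeric(km$centers)
    assign0 <- km$cluster
  }
  w <- tabulate(assign0, K) / n
  w <- pmax(w, 1e-10); w <- w / sum(w)
  v <- vapply(seq_len(K), function(k) {
    xs <- values[assign0 == k]
    if (length(xs) < 2L) vfloor else max(stats::var(xs), vfloor)
  }, numeric(1))

  fit <- .em_gmm(values, w, mu, pmax(v, vfloor), vfloor, tol,
                 as.integer(max_iter))
  if (fit$floored)
    warning("degenerate component(s): variance floored at 1e-6 * var(values)")
  ord <- order(fit$means)
  new_gmm(K, fit$weights[ord], fit$means[ord], fit$variances[ord],
          fit$loglik, n)
}

new_gmm <- function(K, weights, means, variances, loglik, n) {
  structure(
    list(K = K, weights = as.numeric(weights), means = as.numeric(means),
         variances = as.numeric(variances), loglik = loglik,
         bic = -2 * loglik + (3 * K - 1) * log(n), n = n),
    class = "GeneGMM"
  )
}

#' @exportS3Method print GeneGMM
print.GeneGMM <- function(x, ...) {
  cat("GeneGMM: K =", x$K, " BIC =", format(x$bic, digits = 6), "\n")
  cat("  means:", format(x$means, digits = 4), "\n")
  cat("  weights:", format(x$weights, digits = 3), "\n")
  invisible(x)
}

#' Select the number of expression states by BIC
#'
#' Fits mixtures with component counts `k_min` to `k_max` (defaults 2 to 10)
#' and returns the fit with minimal BIC. `k_max` is capped at the number of
#' distinct values; genes with fewer than 3 distinct values fall back to a
#' degenerate single-component model (with a warning) -- such a gene carries
#' no usable state structure and is reported non-SV downstream.
#'
#' @inheritParams fit_gmm
#' @param k_min,k_max range of component counts to consider.
#' @return The `GeneGMM` with the best (lowest) BIC in the range.
#' @export
select_gmm <- function(values, k_min = 2L, k_max = 10L, seed = 1L) {
  values <- as.numeric(values)
  nd <- length(unique(values))
  if (nd < 3L) {
    warning("fewer than 3 distinct values; returning degenerate K = 1 model")
    if (nd < 2L) {
      v <- max(1e-12, 1e-6 * max(abs(values), 1))
      return(new_gmm(1L, 1, values[1L], v,
                     sum(stats::dnorm(values, values[1L], sqrt(v), log = TRUE)),
                     length(values)))
    }
    return(fit_gmm(values, 1L, seed = seed))
  }
  ks <- seq.int(max(1L, k_min), min(k_max, nd, length(values) - 1L))
  fits <- lapply(ks, function(k) fit_gmm(values, k, seed = seed))
  fits[[which.min(vapply(fits, `[[`, numeric(1), "bic"))]]
}

#' Observed expression-state labels
#'
#' Assigns each observation to the mixture component with the highest
#' posterior responsibility. Because components are ordered by ascending
#' mean, labels are ordered by expression level. Posterior ties (e.g. a
#' value exactly midway between two equal-weight, equal-variance components)
#' break toward the lower label.
#'
#' @param gmm a [GeneGMM][fit_gmm].
#' @param values numeric vector.
#' @return Integer labels in `1..K`.
#' @export
initial_labels <- function(gmm, values) {
  stopifnot(inherits(gmm, "GeneGMM"))
  values <- as.numeric(values)
  if (gmm$K == 1L) return(rep(1L, length(values)))
  logpost <- vapply(seq_len(gmm$K), function(k)
    log(gmm$weights[k]) +
      stats::dnorm(values, gmm$means[k], sqrt(gmm$variances[k]), log = TRUE),
    numeric(length(values)))
  if (length(values) == 1L) logpost <- matrix(logpost, nrow = 1L)
  max.col(logpost, ties.method = "first")
}

#' Data penalty matrix
#'
#' The unary term of the segmentation energy: the cost of assigning state
#' `k` to spot `p` is the absolute distance of the spot's expression to the
#' state mean, `U[p, k] = |e_p - mu_k|`. The row minimum is attained at the
#' nearest-mean state.
#'
#' @param values numeric vector of (normalized, log) expression values.
#' @param gmm a [GeneGMM][fit_gmm].
#' @return Numeric n x K matrix.
#' @export
data_penalties <- function(values, gmm) {
  stopifnot(inherits(gmm, "GeneGMM"))
  abs(outer(as.numeric(values), gmm$means, "-"))
}
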