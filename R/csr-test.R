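#' Poisson upper-tail probability
#'
#' Under complete spatial randomness (CSR), points of a given label fall on
#' the graph as a homogeneous Poisson process, so the number of matching
#' points in a `V`-node region is Poisson with mean `lambda = V * rho`. The
#' enrichment p-value is the upper tail `P(X >= k)`, computed stably through
#' the survival function. (The point probability `P(X = k)` is available
#' via `mode = "pmf"` in [segment_pvalue()] for strict fidelity to the
#' quadrat-count formula, but a tail is the standard test statistic.)
#'
#' @param k non-negative integer count.
#' @param lam non-negative Poisson mean.
#' @return `P(X >= k)` for `X ~ Poisson(lam)`.
#' @export
poisson_tail <- function(k, lam) {
  if (any(lam < 0)) stop("'lam' must be non-negative")
  if (any(k < 0)) stop("'k' must be non-negative")
  stats::ppois(k - 1, lam, lower.tail = FALSE)
}

#' CSR test for a single segment
#'
#' Tests whether the observed expression states are enriched in a segment
#' beyond what complete spatial randomness would produce. With `V` the
#' number of nodes in the segment, `a` its hidden label, `rho` the
#' graph-wide density of observed label `a`, and `k` the number of segment
#' nodes whose observed label equals `a`, the p-value is the Poisson tail
#' `P(X >= k)` at mean `V * rho`.
#'
#' @param nodes integer vector of node indices in the segment.
#' @param hidden_label the segment's learned (hidden) label.
#' @param observed_labels integer vector of observed state labels for the
#'   whole graph.
#' @param mode `"tail"` (default, upper tail) or `"pmf"` (point
#'   probability).
#' @return A one-row data frame with columns `V`, `k`, `rho`, `lambda`, `p`.
#' @export
segment_pvalue <- function(nodes, hidden_label, observed_labels,
                           mode = c("tail", "pmf")) {
  mode <- match.arg(mode)
  stopifnot(length(nodes) >= 1L)
  n <- length(observed_labels)
  V <- length(nodes)
  rho <- sum(observed_labels == hidden_label) / n
  k <- sum(observed_labels[nodes] == hidden_label)
  lam <- V * rho
  p <- if (mode == "tail") poisson_tail(k, lam) else stats::dpois(k, lam)
  data.frame(V = V, k = k, rho = rho, lambda = lam, p = min(p, 1))
}

#' Gene-level spatial non-randomness p-value
#'
#' Computes the CSR p-value of every segment of a segmentation and reports
#' the best (minimum). Noise segments -- at most `noise_max_size` nodes AND
#' p >= `noise_min_p` -- are excluded from the minimum when
#' `exclude_noise = TRUE` (a small segment with a strong p-value is not
#' noise and is kept). If no segment is eligible the gene p-value is 1.
#'
#' @param seg a [Segmentation][extract_segments].
#' @param observed_labels integer observed state labels.
#' @param exclude_noise logical (default TRUE).
#' @param noise_max_size,noise_min_p the conjunctive noise rule (defaults
#'   9 nodes and 0.1).
#' @param mode passed to [segment_pvalue()].
#' @return A list with `best_p` and `tests` (data frame with one row per
#'   segment: `V`, `k`, `rho`, `lambda`, `p`, `label`, `noise`).
#' @export
gene_pvalue <- function(seg, observed_labels, exclude_noise = TRUE,
                        noise_max_size = 9L, noise_min_p = 0.1,
                        mode = c("tail", "pmf")) {
  mode <- match.arg(mode)
  stopifnot(inherits(seg, "Segmentation"),
            length(observed_labels) == seg$n)
  tests <- do.call(rbind, lapply(seg$segments, function(s)
    segment_pvalue(s$nodes, s$label, observed_labels, mode = mode)))
  tests$label <- vapply(seg$segments, `[[`, integer(1), "label")
  tests$noise <- tests$V <= noise_max_size & tests$p >= noise_min_p
  eligible <- if (exclude_noise) !tests$noise else rep(TRUE, nrow(tests))
  best_p <- if (any(eligible)) min(tests$p[eligible]) else 1
  list(best_p = best_p, tests = tests)
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up false discovery rate control across all tested genes;
#' the only multiple-testing correction applied (segment p-values within a
#' gene are summarized by their minimum, not corrected).
#'
#' @param pvals numeric vector of p-values in `[0, 1]`.
#' @return Adjusted q-values in the input order, capped at 1 and monotone in
#'   p-value rank.
#' @export
bh_adjust <- function(pvals) {
  stopifnot(all(pvals >= 0 & pvals <= 1))
  stats::p.adjust(pvals, method = "BH")
}
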