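#' Parametric spatial region patterns
#'
#' Optional alternatives to the three-band layout for simulating spatial
#' expression: assigns each coordinate a region id from a named parametric
#' mask. `"bands"` splits the y-range into `k` horizontal bands; `"strip"`
#' marks a central vertical strip (2 regions); `"disk"` marks a central
#' disk covering roughly a third of the area (2 regions); `"quadrants"`
#' splits at the medians (4 regions); `"annulus"` gives center disk, ring,
#' and outside (3 regions). Pass the result as the `regions` argument of
#' [make_benchmark()] (with matching `region_means`).
#'
#' @param coords numeric n x 2 coordinate matrix.
#' @param pattern one of `"bands"`, `"strip"`, `"disk"`, `"quadrants"`,
#'   `"annulus"`.
#' @param k number of bands for `pattern = "bands"`.
#' @return Integer region ids starting at 1.
#' @export
pattern_regions <- function(coords,
                            pattern = c("bands", "strip", "disk",
                                        "quadrants", "annulus"),
                            k = 3L) {
  pattern <- match.arg(pattern)
  coords <- as.matrix(coords)
  x <- coords[, 1L]; y <- coords[, 2L]
  cx <- stats::median(x); cy <- stats::median(y)
  r <- sqrt((x - cx)^2 + (y - cy)^2)
  switch(pattern,
    bands = {
      br <- stats::quantile(y, probs = seq(0, 1, length.out = k + 1L))
      as.integer(cut(y, unique(br), include.lowest = TRUE))
    },
    strip = {
      lo <- stats::quantile(x, 1 / 3); hi <- stats::quantile(x, 2 / 3)
      ifelse(x >= lo & x <= hi, 2L, 1L)
    },
    disk = ifelse(r <= stats::quantile(r, 1 / 3), 2L, 1L),
    quadrants = 1L + (x > cx) + 2L * (y > cy),
    annulus = {
      b <- stats::quantile(r, c(1 / 3, 2 / 3))
      1L + findInterval(r, b)
    })
}

#' Quantile threshold from a reference distance distribution
#'
#' Generic helper for choosing a structure-distance cutoff: genes whose
#' distance to a reference tissue structure falls below the `level` quantile
#' of a reference distribution (e.g. distances of an agreed-upon gene set)
#' are considered concordant with the structure.
#'
#' @param distances numeric vector of reference distances.
#' @param level quantile level in (0, 1], default 0.95.
#' @return The threshold value.
#' @export
distance_threshold <- function(distances, level = 0.95) {
  stopifnot(level > 0, level <= 1, length(distances) >= 1)
  stats::quantile(distances, level, names = FALSE)
}
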