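---
title: "Detecting spatially variable genes with graph-cut optimized Markov random fields"
author: "graphsv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting spatially variable genes with graph-cut optimized Markov random fields}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(graphsv)
```

## The problem

Spatial transcriptomics measures gene expression at spots or single cells
whose planar positions are known. A *spatially variable* (SV) gene is one
whose expression depends on position — it marks a tissue layer, a gradient,
or some other anatomical structure. Testing thousands of genes for spatial
dependence is statistically delicate (what counts as a "region"?) and has to
scale to hundreds of thousands of positions.

`graphsv` takes the explicit-region route: for each gene it *learns*
candidate regions by segmenting a hidden Markov random field (HMRF) over the
spot neighborhood graph, and then tests whether the gene's observed
expression states are enriched in those regions beyond what complete spatial
randomness (CSR) would produce. Regions are learned by exact binary graph
cuts inside an alpha-expansion loop, which is what makes the approach fast
enough to run genome-wide.

## The model

**Neighbor graph.** Spot coordinates are Delaunay-triangulated
(`build_delaunay_graph()`). Delaunay edges connect only authentic neighbors
(no spot lies inside a triangle's circumcircle), so the graph is sparse
(planar: at most $3n-6$ edges) yet captures local adjacency. The Voronoi
tessellation — its dual — is kept for drawing segment boundaries.

**Expression states.** For each gene the log2 expression values are modeled
as a univariate Gaussian mixture
$p(x) = \sum_{k=1}^{K} \pi_k \, \mathcal{N}(x \mid \mu_k, \sigma^2_k)$,
fitted by EM for $K = 2,\dots,10$ and selected by BIC (`select_gmm()`).
Components are ordered by ascending mean, so state labels are ordered by
expression level. Each spot's *observed state* is its maximum-posterior
component (`initial_labels()`).

**Segmentation energy.** Hidden states $x_p$ are estimated by minimizing

$$E(X) = \sum_{p} U_{p, x_p} \;+\; \alpha \sum_{(p,q) \in E} S_{x_p, x_q},$$

with data penalty $U_{p,k} = |e_p - \mu_k|$ (`data_penalties()`) and ordinal
interaction $S_{i,j} = |i-j| \, F$ (`interaction_matrix()`). $S$ is a
metric, so every binary subproblem of alpha-expansion is regular and can be
solved *exactly* as a minimum s–t cut (`min_cut()`, via max-flow). The
expansion move is encoded with the pairwise-decomposition construction
(constant + unary terms + one directed edge per discordant pair), which is
equivalent to the classical auxiliary-node construction but adds no nodes.
For two labels the result is the global optimum; for more labels the
multi-label problem is NP-hard and alpha-expansion returns a strong local
minimum with a known approximation factor. Connected components of equal
hidden label form the *segments* (`extract_segments()`).

**CSR test.** Under the null, spots carrying a given observed state are a
homogeneous Poisson scatter over the graph. For a segment of $V$ nodes with
hidden label $a$, let $\rho$ be the graph-wide density of observed label $a$
and $k$ the number of segment nodes whose observed label is $a$. The count
is $\mathrm{Poisson}(V\rho)$ under CSR, and the segment p-value is the upper
tail $P(X \ge k)$ (`segment_pvalue()`). The mixture formula above writes the
point probability; testing enrichment needs a tail, so the upper tail is the
default and `mode = "pmf"` retains the literal point-probability form. Only
enrichment is tested: depletion of a state inside a segment is not evidence
that the *segment's own* label clusters spatially. A gene's p-value is the
minimum over its (non-noise) segments, and Benjamini–Hochberg correction is
applied across genes (`bh_adjust()`); no within-gene correction is applied
before the minimum, matching the "report the best segment" definition.

**Smooth-factor search.** $\alpha$ is the one free hyperparameter. The
search (`search_smooth_factor()`) walks $\alpha = 10, 20, \dots, 100$,
scoring each segmentation by

$$\mathrm{score} = -\log_{10}(P) - |\text{noise segments}| \cdot \tfrac{200}{n},$$

where noise segments have $\le 9$ nodes *and* $p \ge 0.1$ (a small segment
with a strong p-value is signal, not noise; the rule is conjunctive). The
search stops at the first $\alpha$ whose score is strictly worse than its
predecessor's and returns the best-scoring state seen so far — a worsening
score can still be followed by the best one at the previous step, so
"best seen" rather than "last before worsening" is returned when the
trajectory is non-monotone.

## Parameters and defaults

| parameter | default | meaning |
|---|---|---|
| `pseudocount` | 1 | offset before log2; zeros are ubiquitous in counts |
| `min_spots` | 10 | gene detection filter; a gene in fewer spots cannot support a non-noise segment |
| `k_min`, `k_max` | 2, 10 | GMM component range searched by BIC |
| `penalty_factor` (F) | 0.1 | magnitude of the ordinal interaction |
| `alpha_start`, `alpha_step`, `alpha_max` | 10, 10, 100 | smooth-factor grid (step 5 is the finer alternative) |
| `noise_max_size`, `noise_min_p` | 9, 0.1 | conjunctive noise-segment rule |
| `fdr` | 0.05 | BH reporting threshold |

### Calibrating the interaction magnitude

$F$ and $\alpha$ only enter the energy through their product, so one of
them is redundant scale; the grid over $\alpha$ is fixed at 10–100 and $F$
sets what those values *mean* relative to the data penalties. Log2
expression state means sit roughly one unit apart, so $U$ gaps are of order
one. Two regimes bracket the useful range:

* *Speckle threshold.* A chance same-state cluster of $V$ nodes with
  boundary $B$ edges survives smoothing while
  $\alpha F \cdot B < \sum \Delta U \approx 0.7 V$; with Delaunay geometry
  ($B \gtrsim V$ for small clusters) clusters dissolve once
  $\alpha F \gtrsim 0.7$. Below this, segments are exactly the percolation
  clusters of the observed labels, which the CSR test — correctly — finds
  wildly enriched: a search that can see this regime latches onto chance
  structure and the null calibration is destroyed.
* *Structure collapse.* A genuine region of $V \approx 100$ nodes with
  $B \approx 40$ boundary edges flips to uniform when
  $\alpha F \cdot B > V \cdot \Delta U$, i.e. $\alpha F \gtrsim 2.5$.

$F = 0.1$ places the grid's low end ($\alpha F = 1$) just above the speckle
threshold and lets the grid cross the collapse point, so the score-driven
search starts at the strongest informative smoothing and stops once genuine
structure dissolves. With $F = 1$ the entire grid would sit far beyond
collapse (every gene uniform, nothing detectable); with $F = 0.01$ the
entire grid would sit below the speckle threshold (every gene "significant").
Shuffled-gene datasets generated by `make_benchmark()` confirm the middle
setting: spatially random genes come out with p-values near 0.5 while
region-structured genes retain vanishing p-values. $F$ stays configurable
for data whose penalty scale differs.

## The benchmark simulator

`make_benchmark()` builds a fully labeled test bed with no external data:

* a jittered grid of 262 spots split into three contiguous bands (40/30/30%),
  standing in for a tissue slide with three layers;
* SV genes drawn per spot from $N(0,\sigma^2)$, $N(1,\sigma^2)$,
  $N(2,\sigma^2)$ by region, for $\sigma$ between 0.1 (strong) and 0.6
  (weak);
* null genes as random re-assignments (shuffles) of SV genes' values across
  spots — exactly the same value distribution, zero spatial structure;
* optional Gaussian-noise and random-exchange perturbations;
* an invertible count transform: within-spot shares of $2^{v}$ allocated
  proportionally to a log-normal (median $10^4$) per-spot depth with
  stochastic rounding, so the pipeline's own normalize + log2 recovers the
  simulated values up to an affine map (verified as a round-trip property).

The three-band scheme is the quantitative, tested path. A `layout` hook on
`make_benchmark()` accepts any `(coords, regions)` pair — real slide
coordinates, or the optional parametric masks of `pattern_regions()`
(strips, disks, quadrants, annuli) for qualitative variety.

What it does *not* emulate: real spot geometries (hexagonal arrays, tissue
holes), gene–gene correlation, zero inflation, and technology-specific
noise. Passing the benchmark therefore demonstrates the machinery — state
calling, segmentation, calibration of the CSR test, the search dynamics —
not robustness to every artifact of real slides.

One compositional caveat: the count transform allocates each spot's depth
across genes by *share*, so a panel in which every gene carries the same
regional pattern cancels its own signal in the within-spot denominator (as
real library-size normalization would). Benchmarks therefore always mix SV
genes with shuffled nulls, which dominate the denominator and leave the
regional signal intact — also the realistic regime, since most genes in a
real transcriptome are not layer-specific.

Test and benchmark problem sizes are chosen at desk scale: 262 spots with
100 SV + 900 null genes for the power/FPR runs, 100 SV + 400 null genes per
noise level for the degradation comparison, and n up to ~1000 spots for
scaling checks.

## Numerical and design choices

* *EM details*: seeded k-means initialization; convergence at $10^{-4}$
  absolute log-likelihood change, at most 200 iterations; component
  variances floored at $10^{-6} \cdot \mathrm{var}(x)$ (warning when the
  floor binds); BIC uses $3K - 1$ free parameters. Posterior ties and exact
  midpoints assign the lower (lower-expression) state.
* *Degenerate genes*: fewer than 3 distinct values → a $K=1$ model, one
  all-graph segment, $p = 1$; the gene is reported, never dropped.
* *Score guard*: $-\log_{10}(p)$ is evaluated with $p$ floored at
  $10^{-300}$ so an underflowing tail cannot produce an infinite score.
* *Expansion determinism*: labels are visited in ascending order, moves are
  accepted only on strict energy decrease, so runs are exactly reproducible
  without randomness; per-gene seeds (for GMM initialization) derive from
  the global seed and gene index, making results independent of worker
  count.
* *Observed labels are fixed per gene*: segment p-values at every $\alpha$
  reuse the GMM labels; they are never refit during the search.
* *Noise segments are excluded* from the gene-level minimum p by default
  (configurable); a gene whose only segments are noise reports $p = 1$.
* *Duplicate coordinates* are rejected with the offending spot ids, not
  jittered — silent jitter would fabricate geometry.
* *Reconstruction* (`reconstruct_tissue()`) clusters spots by k-means on SV
  gene profiles and refines with one graph-cut optimization; cluster labels
  are nominal, so the Potts interaction (constant penalty for any
  disagreement) is the default there, with the ordinal form behind a flag.
  Its default smooth factor is 1, not the gene-level grid values: the data
  penalties here are Euclidean distances in $g$-dimensional gene space
  (scale $\sim \sqrt{g}$), so smoothing must stay below the
  centroid-separation scale to refine the clustering rather than erase it.
  Accuracy against reference layers uses maximum-overlap matching (several
  clusters may map to one layer); optimal one-to-one matching is available
  behind a flag.
* *Hull Voronoi ridges* are clipped to the bounding box expanded by 5% for
  drawing; zero-length (degenerate, cocircular) dual ridges are dropped.
  Clipping affects only figures, never statistics.

## Limitations

* The smooth-factor search is sequential and can stop at a local optimum of
  the score; a non-monotone score landscape beyond the first worsening step
  is never explored.
* Multi-label energies are minimized approximately (NP-hard in general);
  the two-label case is exact.
* The CSR null assumes a homogeneous point process over the graph; strongly
  inhomogeneous spot densities would need an inhomogeneous baseline, which
  is out of scope.
* 2-D only; no 3-D triangulation.
* The Poisson tail is discrete and conservative for small segments, which
  is the safe direction for FDR control.

## A minimal run

```{r example, eval = FALSE}
bm <- make_benchmark(n_sv = 100, n_null = 900, sigma = 0.3, seed = 1)
res <- run_pipeline(bm, pipeline_config(seed = 1))
confusion_metrics(bm$truth, res$table$called)
```
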