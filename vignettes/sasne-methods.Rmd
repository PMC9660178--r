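---
title: "Shape-aware stochastic neighbor embedding: model, choices, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Shape-aware stochastic neighbor embedding: model, choices, and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

t-SNE and its relatives embed high-dimensional data by matching a
probability distribution over pairs of points in the input space with one in
the plane. The input distribution is built from distances, and conventional
distances — Euclidean above all — are only trustworthy inside small local
neighborhoods: on curved or branched structures they misjudge every remote
comparison. In practice this forces a small perplexity (the effective
neighbor count of the Gaussian kernel), which in turn produces embeddings
that shred global and hierarchical organisation and can invent spurious
clusters.

This package takes the opposite route. It replaces the input distances with
a *shape-aware* graph distance — the biharmonic distance of a
minimally-connected k-nearest-neighbor graph — which is globally valid
because it propagates only through local connections. With a globally valid
metric the perplexity can be made very large (90% of the number of points by
default), turning the only tuning knob of t-SNE into a data-driven constant.

## The pipeline

`sasne(x)` composes four stages, each available separately:

1. **Graph construction** (`knn_edges`, `minimal_connected_k`,
   `adaptive_graph`). Each point is joined to its k nearest Euclidean
   neighbors; the edge set is union-symmetrised (an edge exists if either
   endpoint lists the other). Edge weights are inverse squared distances,
   `w_ij = 1 / ||x_i - x_j||^2` — deliberately kernel-free, so no bandwidth
   parameter enters. k itself is chosen as the smallest value for which the
   graph is connected, found by scanning k upward from 1; on
   single-component clouds this lands near 5. When widely separated regions
   force a large k, `adaptive_graph` recurses: it keeps only the edges of
   the connected kNN graph that bridge distinct components of the (k-1)NN
   graph and re-runs the construction inside each component, so that
   neighborhood sizes stay local everywhere while the bridges preserve
   global connectivity.
2. **Biharmonic distances** (`graph_laplacian`, `laplacian_spectrum`,
   `biharmonic_distances`). From the combinatorial Laplacian `L = D - W`
   and its eigenpairs `(lambda_k, phi_k)`, the squared biharmonic distance
   is `sum_{k >= 2} (phi_k(i) - phi_k(j))^2 / lambda_k^2` — the quadratic
   form of the squared pseudo-inverse. The commute-time distance (weights
   `1 / lambda_k`) is provided for cross-checks; the steeper biharmonic
   weighting damps high-frequency modes, which stabilises large-distance
   estimates and widens the gap between within-cluster and between-cluster
   distances.
3. **Affinities and optimisation** (`conditional_affinities`,
   `tsne_optimize`). Standard t-SNE machinery operating on any distance
   matrix: per-point Gaussian bandwidths calibrated by bisection to a fixed
   perplexity, symmetrised joint probabilities, Student-t output kernel,
   and momentum gradient descent on the Kullback-Leibler divergence with
   early exaggeration and per-coordinate adaptive gains.
4. **Validation** (`rank_matrix`, `mare`, `rrp`, `silhouette_report`).
   Quantitative quality measures, described below.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `k_cap` | 5 | recursion threshold of `adaptive_graph`; the "local" neighborhood size the recursion drives components back to |
| `perplexity` | `min(0.9 n, n - 2)` | effective neighbor count of the Gaussian input kernel |
| `iters` | 1000 | gradient iterations |
| `lr` | `max(n / 12, 50)` | learning rate of the optimiser |
| `exaggeration` | 12 (first 250 iterations) | transient multiplication of input affinities |
| `momentum` | 0.5 then 0.8 (switch at 250) | optimiser momentum schedule |

The 90% perplexity rule deserves emphasis: it is only sensible *because*
the biharmonic distance is globally valid, and leaving out the last 10%
keeps outliers from inflating the kernel bandwidths. Perplexity equal to
`n - 1` is the infinite-bandwidth limit (uniform conditionals) and values
beyond it are unattainable, so the default caps at `n - 2`, where the
entropy bisection still brackets strictly. When you embed a *Euclidean*
distance matrix with `tsne_embed` as a baseline, the classical default
perplexity of 30 is the appropriate comparison setting, and that is what
the package's benchmark comparisons use for the baseline.

The optimisation schedule follows the original t-SNE optimiser. Because
inputs are distance matrices rather than coordinates, initial positions
cannot come from principal components; they are drawn from an isotropic
Gaussian with standard deviation 1e-4 under the caller's seed, making every
run reproducible bit-for-bit.

## Validation statistics

Two complementary views of embedding quality:

* **Silhouette under an arbitrary distance.** For point i in cluster `C_k`,
  cohesion `a_i` is the mean distance to members of its own cluster and
  separation `b_i` the mean distance to the nearest other cluster;
  `s_i = (b_i - a_i) / max(a_i, b_i)` lies in [-1, 1]. The cohesion sum is
  implemented exactly as stated — running over *all* of `C_k` including the
  point itself, divisor `N_k`. The classical self-excluded convention
  (divisor `N_k - 1`) is available via `convention = "rousseeuw"`; with
  fully coincident points (`max(a_i, b_i) = 0`) the value is defined as 0,
  since the literal formula would otherwise reward degenerate clusters.
  Cluster scores are member means; the coefficient is the unweighted mean
  over clusters, so small clusters are not drowned out — the point of the
  imbalanced benchmark.
* **Rank preservation.** For each point, all others are ranked by distance
  in the input space and in the embedding (ties broken by sample index,
  identically on both sides). The mean absolute rank error of point i is
  the mean of `|r_x - r_y| / (n - 1)` over the other points, and the
  average rank error is its mean over points. Both lie in [0, 1]; note the
  normalisation bound of 1 is attained per *pair*, not per mean — a
  complete rank reversal of a row yields a point-wise value of about 1/2.
  The value is implemented exactly as defined, bound included, rather than
  renormalised. The rank residual plot (`rrp`) is a 2D histogram of
  normalised residuals `(r_x - r_y) / (n - 1)` against normalised input
  rank `r_x / (n - 1)` (the rank-value reading of the abscissa; after
  sorting it coincides with the neighbor-index reading): local distortion
  shows on the left, global distortion on the right, and a perfect
  embedding is a flat ridge at zero. Bins are colored by global relative
  density, with empty (unreachable) cells left white.

When comparing methods, each embedding is scored against the distance it
consumed — biharmonic for the shape-aware run, Euclidean for the baseline —
mirroring how the silhouette's distance is chosen per method.

## The synthetic benchmarks

Four generators cover the failure modes the method targets. All are
deterministic given a seed, store their complete generative truth, and
accept overrides; the defaults are frozen and asserted in the test suite.

* `gen_imbalanced`: 1000 + 50 points from two 3D Gaussians with identical
  isotropic covariance and means 5 standard deviations apart. Tests whether
  a small cluster survives next to a large one.
* `gen_nonlinear`: 2 × 400 points sampled uniformly along two radius-5
  half-circle arcs in orthogonal planes, endpoints offset so the minimum
  curve-curve gap (about 2) is more than six times the noise scale
  (sigma = 0.3). Tests unrolling of 1D nonlinear structure.
* `gen_hierarchical`: 6 × 100 points from equal-covariance 3D Gaussians
  whose means form two triads (group centers 12 apart, within-group
  offsets 3), so every within-group mean distance is strictly below every
  between-group distance. Tests preservation of cluster hierarchy.
* `gen_tree`: 1440 points on a 10-segment piecewise-linear recursive tree
  in 60 dimensions. The first segment grows from the origin along the
  first coordinate; each later segment starts at the endpoint of a
  randomly chosen (seeded) earlier segment and extends length 20 along its
  own coordinate, emulating developmental trajectories that branch off in
  various directions — the construction style of the artificial-tree
  benchmarks used for trajectory methods. The manifold occupies the first
  10 of 60 dimensions; Gaussian noise (sigma = 0.5) is added to all 60.
  Segment lengths are chosen so the manifold dominates the aggregate noise
  radius (roughly `sqrt(60) * 0.5 ≈ 3.9`) — with much shorter branches the
  tree would be statistically unrecoverable by any method — and the
  recursive topology avoids a single dominant path, whose middle the
  heavily low-frequency-weighted biharmonic metric would otherwise stretch
  into an artificial low-density gap. Tests whether continuous
  trajectories stay intact instead of being shattered into spurious
  clusters.

What these generators do *not* emulate: heavy-tailed count noise, dropout,
batch structure, or the high ambient dimensionality of real transcriptomic
matrices. Passing benchmarks here demonstrates the geometric claims —
shape-aware distances preserve global ordering and trajectories — not
robustness to the full noise anatomy of single-cell data.

## Numerical choices

* **Coincident points** give infinite inverse-square weights; squared
  distances are floored at `1e-12` times the median nonzero squared
  neighbor distance, with a warning. Samples are never merged silently.
* **Ties** in neighbor search and ranking are broken by ascending sample
  index with stable sorts, so identical inputs yield identical outputs.
* **Null-space detection** uses `zero_tol = n * eps * lambda_max`. A
  connected graph must show exactly one eigenvalue under the tolerance;
  any other count raises an error rather than a silent repair.
* **Eigendecomposition** is full and dense (O(n^3)); the whole pipeline is
  O(n^2) in memory by design and intended for desk-scale n (up to a few
  thousand). The package deliberately avoids Barnes-Hut/interpolation
  accelerations, which presume small perplexities.
* **Degenerate affinity rows** (all distances equal) have
  bandwidth-independent entropy; the uniform conditional is returned
  instead of an error.
* **KL evaluation** floors `q` at 1e-12 inside the cost/gradient only; the
  stored distributions are never modified.
* The problem sizes exercised in the test suite (up to n = 1440 for the
  full benchmarks, n ≤ 50 for oracle cross-checks against dense
  pseudo-inverses) keep every oracle comparison exact while the full
  benchmark runs remain minutes-scale.

## Known limitations

* O(n^2) memory and O(n^3) spectral cost bound n; graph coarse-graining or
  iterative eigensolvers would be needed beyond desk scale.
* On densely sampled one-dimensional manifolds the minimal-connectivity
  rule returns very small k (filaments connect at k = 2-3), and the
  resulting Laplacian has a near-degenerate low end
  (`lambda_2 ~ 1e-5`). Because the biharmonic weighting is `1 / lambda^2`,
  the metric then collapses onto its few lowest modes and exaggerates the
  tree's spectral bottlenecks into near-discrete gaps — the same property
  that sharpens genuine cluster boundaries can locally thin out a
  continuous trajectory around the structure's center. Branches remain
  visually contiguous filaments, but nearest-neighbor graphs built on the
  embedding can split across these low-density stretches. A denser graph
  (k around 5, the value the connectivity rule typically lands on for
  cluster-structured data) removes the degeneracy; if trajectory data
  connect at k below that, consider passing `knn_edges(x, k = 5)` to
  `sasne()` explicitly.
* The minimal-connected-k rule is sensitive to a single far outlier, which
  can inflate k for the whole dataset; `adaptive_graph` mitigates exactly
  this, but an outlier that is far from *everything* still ends up with a
  long bridge edge whose tiny weight dominates no distance yet stretches
  the embedding.
* Only the Euclidean metric is implemented for the neighbor search; the
  interface accepts a metric name so that, e.g., Hamming or count-model
  distances can be added without touching callers.
* The silhouette's literal cohesion (self-inclusive, divisor `N_k`) gives
  singletons `a_i = 0` and hence `s_i = 1`; this follows the definition as
  printed, and the classical convention is one switch away. Interpret
  singleton scores accordingly.
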