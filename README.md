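# sasne

Shape-aware stochastic neighbor embedding for high-dimensional biological
data — t-SNE driven by biharmonic graph distances instead of Euclidean
ones, with a quantitative validation toolkit.

## The problem and the method

Distance measures like the Euclidean distance are only reliable within
small local neighborhoods of a curved or branched data manifold, which is
why classical t-SNE must run at small perplexity and consequently loses
global and hierarchical structure (and can invent clusters that are not
there). `sasne` replaces the input distances with a *shape-aware* graph
metric and then lets the perplexity be large:

1. Build a kNN similarity graph with union-symmetrised edges and weights
   `w_ij = 1 / ||x_i − x_j||²`, choosing k as the smallest value that keeps
   the graph connected (with a recursive refinement when distant regions
   would force a large k).
2. From the graph Laplacian `L = D − W` with eigenpairs `(λ_k, φ_k)`,
   compute the biharmonic distance
   `d_B(i,j)² = Σ_{k≥2} (φ_k(i) − φ_k(j))² / λ_k²`.
3. Run the standard t-SNE core (perplexity-calibrated Gaussian affinities,
   Student-t output kernel, KL gradient descent) on that distance matrix,
   at a perplexity of 90% of the number of points.

Embedding quality is measured by the **average rank error**
`R̄ = mean_i mean_j |r^x_ij − r^y_ij| / (n−1)` between input-space and
embedding-space neighbor ranks (0 = perfect rank preservation), the
corresponding **rank residual plot**, and **silhouette statistics**
`s_i = (b_i − a_i) / max(a_i, b_i)` computed under any distance matrix.

Who it is for: anyone embedding desk-scale (up to a few thousand samples)
expression matrices, single-cell profiles, or other high-dimensional
tabular data who needs the global arrangement of clusters and trajectories
to survive the projection — and wants numbers, not eyeballing, to judge it.

## Worked example

```r
library(sasne)

ds <- gen_hierarchical(seed = 1)        # 6 Gaussian clusters in two triads
emb <- sasne(ds, iters = 500, seed = 1) # graph -> biharmonic -> t-SNE
emb
#> <sasne_embedding> 600 points, biharmonic distances, perplexity 540, 500 iterations, final KL 2.22e-08

# rank preservation, scored against the distances the method embedded
h <- rrp(rank_matrix(emb$distances), rank_matrix(emb))
h
#> <sasne_rrp> 600 points, 100 x 100 bins, average rank error 0.0602

# the Euclidean t-SNE baseline at its classical perplexity default
De  <- euclidean_distances(ds)
emb_tsne <- tsne_embed(De, perplexity = 30, iters = 500, seed = 1)
h_tsne <- rrp(rank_matrix(De), rank_matrix(emb_tsne))

compare_runs(list(
  sasne = list(rrp = h,      silhouette = silhouette_report(emb$distances, ds$labels)),
  tsne  = list(rrp = h_tsne, silhouette = silhouette_report(De, ds$labels))
))
#> # A tibble: 2 × 3
#>   name  avg_rank_error silhouette
#>   <chr>          <dbl>      <dbl>
#> 1 sasne         0.0602      0.690
#> 2 tsne          0.150       0.474
```

The shape-aware run preserves distance ranks about 2.5× better than the
Euclidean baseline on this benchmark (average rank error 0.06 vs 0.15) and
separates the labelled clusters more cleanly under its own distance
(silhouette coefficient 0.69 vs 0.47). `autoplot(emb, labels = ds$labels)`,
`plot_rrp(h)` and `plot_silhouette(...)` draw the embedding, the rank
residual histogram and the silhouette bars.

A command-line interface wraps the same pipeline
(`system.file("exec", "sasne", package = "sasne")`) with subcommands
`simulate`, `embed`, `validate`, `compare`.

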