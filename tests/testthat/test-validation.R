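test_that("rank matrix orders neighbors with stable index tie-breaks", {
  # 3 points on a line at 0, 1, 3
  D <- euclidean_distances(matrix(c(0, 1, 3), ncol = 1))
  R <- rank_matrix(D)
  expect_equal(R[1, ], c(0L, 1L, 2L))
  expect_equal(R[2, ], c(1L, 0L, 2L))
  expect_equal(R[3, ], c(2L, 1L, 0L))
  # all-equal distances: ascending index order
  De <- matrix(1, 4, 4); diag(De) <- 0
  Re <- rank_matrix(De)
  expect_equal(Re[1, ], c(0L, 1L, 2L, 3L))
  expect_equal(Re[4, ], c(1L, 2L, 3L, 0L))
  # every row is a permutation of 1..n-1
  Rr <- rank_matrix(rand_dist(17, seed = 5))
  for (i in 1:17) expect_setequal(Rr[i, -i], 1:16)
})

test_that("MARE is zero on identical ranks and 0.5 on a full reversal row", {
  R <- rank_matrix(rand_dist(12, seed = 1))
  m <- mare(R, R)
  expect_equal(m$per_point, rep(0, 12))
  expect_equal(m$overall, 0)
  # n = 5: one row fully reversed gives (3+1+1+3)/16 = 0.5
  R5 <- rank_matrix(rand_dist(5, seed = 2))
  Ry <- R5
  i <- 1
  Ry[i, -i] <- 5 - R5[i, -i]  # rank r -> 5 - r reverses 1..4
  m5 <- mare(R5, Ry)
  expect_equal(m5$per_point[1], 0.5)
  expect_equal(m5$per_point[-1], rep(0, 4))
})

test_that("MARE matches the naive double-loop oracle on random permutations", {
  for (seed in 1:5) {
    n <- withr::with_seed(seed, sample(5:40, 1))
    Rx <- rank_matrix(rand_dist(n, seed = seed + 10))
    Ry <- rank_matrix(rand_dist(n, seed = seed + 60))
    got <- mare(Rx, Ry)
    want <- oracle_mare(Rx, Ry)
    expect_equal(got$per_point, want$per_point, tolerance = 1e-12)
    expect_equal(got$overall, want$overall, tolerance = 1e-12)
    expect_true(all(got$per_point >= 0 & got$per_point <= 1))
  }
})

test_that("MARE is invariant under a common permutation of the samples", {
  Rx <- rank_matrix(rand_dist(20, seed = 3))
  Ry <- rank_matrix(rand_dist(20, seed = 33))
  base <- mare(Rx, Ry)$overall
  perm <- withr::with_seed(4, sample(20))
  # permuting samples permutes rows and relabels columns of both rank matrices
  expect_equal(mare(Rx[perm, perm], Ry[perm, perm])$overall, base,
               tolerance = 1e-12)
})

test_that("rank residual histogram counts every ordered pair once", {
  n <- 18
  Rx <- rank_matrix(rand_dist(n, seed = 6))
  Ry <- rank_matrix(rand_dist(n, seed = 66))
  h <- rrp(Rx, Ry, n_bins = 25)
  expect_equal(sum(h$bins), n * (n - 1))
  expect_equal(h$average_rank_error, mare(Rx, Ry)$overall)
  # perfect preservation: all mass on the zero-residual row
  h0 <- rrp(Rx, Rx, n_bins = 25)
  expect_equal(sum(h0$bins), n * (n - 1))
  mid <- findInterval(0, h0$y_edges)
  expect_equal(sum(h0$bins[mid, ]), n * (n - 1))
  expect_equal(h0$average_rank_error, 0)
  # residuals strictly inside (-1, 1): bounded by (n-2)/(n-1) in magnitude
  off <- row(Rx) != col(Rx)
  resid <- (Rx[off] - Ry[off]) / (n - 1)
  expect_lte(max(abs(resid)), (n - 2) / (n - 1))
})

test_that("silhouette reproduces the 4-point worked example exactly", {
  # two clusters of two: within-pair distance 1, across 10
  D <- matrix(10, 4, 4)
  D[1, 2] <- D[2, 1] <- 1
  D[3, 4] <- D[4, 3] <- 1
  diag(D) <- 0
  s <- silhouette_report(D, c(1, 1, 2, 2))
  expect_equal(s$point_values, rep(0.95, 4))
  expect_equal(unname(s$cluster_scores), c(0.95, 0.95))
  expect_equal(s$coefficient, 0.95)
  # classical convention excludes the self term: a = 1, s = 0.9
  sr <- silhouette_report(D, c(1, 1, 2, 2), convention = "rousseeuw")
  expect_equal(sr$point_values, rep(0.9, 4))
})

test_that("silhouette handles degenerate and invalid inputs", {
  D0 <- matrix(0, 4, 4)
  s <- silhouette_report(D0, c(1, 1, 2, 2))
  expect_equal(s$point_values, rep(0, 4))
  expect_error(silhouette_report(rand_dist(5), rep(1, 5)), "two clusters")
})

test_that("silhouette values stay in [-1, 1] and match the oracle on fuzz", {
  for (seed in 1:8) {
    n <- withr::with_seed(seed, sample(6:40, 1))
    D <- rand_dist(n, seed = seed + 5)
    labels <- withr::with_seed(seed, {
      k <- sample(2:4, 1)
      c(seq_len(k), sample(k, n - k, replace = TRUE))  # every cluster nonempty
    })
    s <- silhouette_report(D, labels)
    expect_true(all(s$point_values >= -1 & s$point_values <= 1))
    expect_equal(s$point_values, oracle_silhouette(D, labels),
                 tolerance = 1e-12)
    # cluster scores are member means; coefficient is their unweighted mean
    for (k in unique(labels)) {
      expect_equal(unname(s$cluster_scores[as.character(k)]),
                   mean(s$point_values[labels == k]))
    }
    expect_equal(s$coefficient, mean(s$cluster_scores))
  }
})

test_that("BHD silhouette beats ED silhouette on hierarchical structure", {
  wins <- 0L
  for (seed in 1:3) {
    ds <- gen_hierarchical(seed = seed, n_per_cluster = 40)
    B <- biharmonic_distances(adaptive_graph(ds$data))
    sb <- silhouette_report(B, ds$labels)$coefficient
    se <- silhouette_report(euclidean_distances(ds$data), ds$labels)$coefficient
    if (sb > se) wins <- wins + 1L
  }
  expect_gte(wins, 2L)
})

test_that("compare_runs tabulates reports and leaves missing slots NA", {
  Rx <- rank_matrix(rand_dist(10, seed = 1))
  Ry <- rank_matrix(rand_dist(10, seed = 2))
  h <- rrp(Rx, Ry, n_bins = 10)
  s <- silhouette_report(rand_dist(10, seed = 3), rep(1:2, 5))
  tab <- compare_runs(list(
    full = list(rrp = h, silhouette = s),
    unlabelled = list(rrp = h)
  ))
  expect_equal(nrow(tab), 2)
  expect_equal(tab$name, c("full", "unlabelled"))
  expect_equal(tab$avg_rank_error, rep(h$average_rank_error, 2))
  expect_equal(tab$silhouette, c(s$coefficient, NA))
})

test_that("plot builders return ggplot objects", {
  Rx <- rank_matrix(rand_dist(10, seed = 4))
  h <- rrp(Rx, rank_matrix(rand_dist(10, seed = 5)), n_bins = 10)
  expect_s3_class(plot_rrp(h), "ggplot")
  s <- silhouette_report(rand_dist(10, seed = 6), rep(1:2, 5))
  expect_s3_class(plot_silhouette(s), "ggplot")
})
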