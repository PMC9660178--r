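test_that("default perplexity is 90 percent of n, capped at n - 2", {
  expect_equal(default_perplexity(1000), 900)
  expect_equal(default_perplexity(10), 8)
  expect_equal(default_perplexity(1440), 1296)
  expect_error(default_perplexity(3), "at least 4")
})

test_that("affinities: equilateral worked example and normalisation", {
  tri <- rbind(c(0, 0), c(1, 0), c(0.5, sqrt(3) / 2))
  a <- conditional_affinities(euclidean_distances(tri), perplexity = 2)
  off <- row(a$p) != col(a$p)
  expect_equal(unname(a$p[off]), rep(1 / 6, 6), tolerance = 1e-10)
  expect_equal(sum(a$p), 1, tolerance = 1e-10)
})

test_that("per-point perplexity is attained and the joint sums to one", {
  for (perp in c(5, 15, 30)) {
    D <- rand_dist(40, seed = perp)
    a <- conditional_affinities(D, perp)
    expect_equal(sum(a$p), 1, tolerance = 1e-10)
    expect_symmetric(a$p)
    expect_true(all(diag(a$p) == 0))
    expect_lt(max(abs(a$achieved / perp - 1)), 1e-4)
  }
})

test_that("affinities are invariant under rescaling of the distances", {
  D <- rand_dist(25, seed = 3)
  a1 <- conditional_affinities(D, 10)
  a2 <- conditional_affinities(2 * D, 10)
  expect_equal(a1$p, a2$p, tolerance = 1e-10)
  expect_equal(a2$sigmas, 2 * a1$sigmas, tolerance = 1e-6)
})

test_that("out-of-range perplexity is rejected", {
  D <- rand_dist(10)
  expect_error(conditional_affinities(D, 1.5), "perplexity")
  expect_error(conditional_affinities(D, 10), "perplexity")
})

test_that("rows of all-equal distances give the uniform conditional", {
  D <- matrix(1, 5, 5); diag(D) <- 0
  a <- conditional_affinities(D, 3)
  expect_equal(unname(a$p[1, -1]), rep(1 / 20, 4), tolerance = 1e-10)
  expect_equal(sum(a$p), 1, tolerance = 1e-10)
})

test_that("low-dimensional affinities follow the Student-t kernel", {
  # two points: the single pair carries all mass regardless of separation
  q2 <- low_dim_affinities(rbind(c(0, 0), c(7, 0)))
  expect_equal(q2$q[1, 2], 0.5)
  # equilateral: all pairs equal
  q3 <- low_dim_affinities(rbind(c(0, 0), c(1, 0), c(0.5, sqrt(3) / 2)))
  off <- row(q3$q) != col(q3$q)
  expect_equal(unname(q3$q[off]), rep(1 / 6, 6), tolerance = 1e-12)
  # generic coords: normalised, symmetric, kernel value checked directly
  y <- rand_cloud(15, d = 2, seed = 2)
  q <- low_dim_affinities(y)
  expect_equal(sum(q$q), 1, tolerance = 1e-12)
  d2_12 <- sum((y[1, ] - y[2, ])^2)
  expect_equal(q$q[1, 2], (1 / (1 + d2_12)) / q$Z, tolerance = 1e-12)
})

test_that("KL divergence: identity, hand-computed value, nonnegativity", {
  q <- low_dim_affinities(rand_cloud(8, 2, seed = 4))$q
  expect_equal(kl_divergence(q, q), 0)
  # three-pair hand example (as flat distributions over 3 cells)
  p <- matrix(c(1 / 3, 1 / 3, 1 / 3), 1)
  qq <- matrix(c(1 / 2, 1 / 4, 1 / 4), 1)
  expect_equal(kl_divergence(p, qq),
               sum((1 / 3) * log((1 / 3) / c(1 / 2, 1 / 4, 1 / 4))))
  # Gibbs inequality on random pairs
  for (seed in 1:4) {
    pr <- withr::with_seed(seed, {
      m <- matrix(runif(36), 6); diag(m) <- 0; m / sum(m)
    })
    expect_gte(kl_divergence(pr, q <- {
      m2 <- withr::with_seed(seed + 50, matrix(runif(36), 6))
      diag(m2) <- 0; m2 / sum(m2)
    }), 0)
  }
  expect_error(kl_divergence(matrix(c(0.5, 0.5), 1), matrix(c(1, 0), 1)),
               "undefined")
})

test_that("optimiser separates well-separated groups and descends the cost", {
  # two tight triads; perplexity 2 concentrates all affinity within groups,
  # and the toy size calls for a small learning rate
  x <- rbind(c(0, 0), c(0.1, 0), c(0, 0.1),
             c(50, 0), c(50.1, 0), c(50, 0.1))
  a <- conditional_affinities(euclidean_distances(x), 2)
  emb <- tsne_optimize(a, iters = 400, seed = 2, lr = 1)
  Y <- emb$coords
  intra <- max(dist(Y[1:3, ]), dist(Y[4:6, ]))
  inter <- min(as.matrix(dist(Y))[1:3, 4:6])
  expect_gt(inter / intra, 5)
  # cost descends after the exaggeration phase ends
  ex_end <- emb$params$exaggeration_iter
  post <- emb$kl_trace[(ex_end + 1):length(emb$kl_trace)]
  expect_lt(tail(post, 1), post[1] + 1e-12)
  expect_true(all(diff(post) < 1e-3))
  expect_true(all(is.finite(Y)))
})

test_that("optimisation is bit-identical under a fixed seed", {
  a <- conditional_affinities(rand_dist(20, seed = 6), 10)
  e1 <- tsne_optimize(a, iters = 60, seed = 9)
  e2 <- tsne_optimize(a, iters = 60, seed = 9)
  expect_identical(e1$coords, e2$coords)
  expect_identical(e1$kl_trace, e2$kl_trace)
  e3 <- tsne_optimize(a, iters = 60, seed = 10)
  expect_false(identical(e1$coords, e3$coords))
})

test_that("KL cost is invariant under rigid motion of the embedding", {
  a <- conditional_affinities(rand_dist(12, seed = 7), 6)
  y <- rand_cloud(12, 2, seed = 8)
  theta <- 0.7
  rot <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2)
  y2 <- sweep(y %*% rot, 2, c(3, -1), "+")
  expect_equal(kl_divergence(a, low_dim_affinities(y)$q),
               kl_divergence(a, low_dim_affinities(y2)$q),
               tolerance = 1e-10)
})

test_that("sasne pipeline runs end to end, deterministically, on a square", {
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  emb <- sasne(sq, iters = 30, seed = 1)
  expect_true(all(is.finite(emb$coords)))
  expect_equal(dim(emb$coords), c(4, 2))
  emb2 <- sasne(sq, iters = 30, seed = 1)
  expect_identical(emb$coords, emb2$coords)
  expect_s3_class(tidy(emb), "tbl_df")
  expect_equal(nrow(tidy(emb)), 4)
  expect_equal(glance(emb)$n, 4)
})

test_that("raising perplexity does not hurt rank preservation on curves", {
  # small draw from the nonlinear benchmark; nonstrict monotone trend over
  # three perplexity levels, majority over seeds
  wins <- 0L
  for (seed in 1:3) {
    ds <- gen_nonlinear(seed = seed, n_per_curve = 75)
    g <- adaptive_graph(ds$data)
    B <- biharmonic_distances(g)
    Rb <- rank_matrix(B)
    errs <- vapply(c(30, 75, 135), function(perp) {
      e <- tsne_embed(B, perplexity = perp, iters = 300, seed = seed)
      mare(Rb, rank_matrix(e))$overall
    }, numeric(1))
    if (errs[3] <= errs[1] + 0.01) wins <- wins + 1L
  }
  expect_gte(wins, 2L)
})
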