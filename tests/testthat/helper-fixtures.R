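# Shared fixtures and independent oracles. Oracles are deliberately naive
# (double loops, dense pseudo-inverses) and share no code with the package
# internals they check.

# random point cloud
rand_cloud <- function(n, d = 3, seed = 1) {
  withr::with_seed(seed, matrix(rnorm(n * d), n, d))
}

# random connected weighted graph: random points -> kNN at a k that connects
rand_connected_graph <- function(n, seed = 1) {
  x <- rand_cloud(n, d = 2, seed = seed)
  knn_edges(x, k = minimal_connected_k(x))
}

# distance matrix from random points (always a valid metric)
rand_dist <- function(n, d = 4, seed = 1) {
  as.matrix(dist(rand_cloud(n, d, seed)))
}

# oracle: brute-force spectral-free BHD via dense pseudo-inverse of L
# (squaring the pseudo-inverse, not pseudo-inverting L^2: the latter loses
# near-null modes to ginv's singular-value cutoff on weakly coupled graphs)
oracle_bhd <- function(W) {
  W <- as.matrix(W)
  L <- diag(rowSums(W)) - W
  Lp <- MASS::ginv(L)
  L2p <- Lp %*% Lp
  n <- nrow(W)
  D <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      e <- numeric(n); e[i] <- 1; e[j] <- e[j] - 1
      D[i, j] <- sqrt(max(drop(t(e) %*% L2p %*% e), 0))
    }
  }
  D
}

# oracle: commute-time / effective-resistance distance via pseudo-inverse
oracle_ctd <- function(W) {
  W <- as.matrix(W)
  L <- diag(rowSums(W)) - W
  Lp <- MASS::ginv(L)
  n <- nrow(W)
  D <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      e <- numeric(n); e[i] <- 1; e[j] <- e[j] - 1
      D[i, j] <- sqrt(max(drop(t(e) %*% Lp %*% e), 0))
    }
  }
  D
}

# oracle: naive MARE by explicit loops
oracle_mare <- function(Rx, Ry) {
  n <- nrow(Rx)
  per <- numeric(n)
  for (i in seq_len(n)) {
    acc <- 0
    for (j in seq_len(n)) {
      if (j != i) acc <- acc + abs(Rx[i, j] - Ry[i, j]) / (n - 1)
    }
    per[i] <- acc / (n - 1)
  }
  list(per_point = per, overall = mean(per))
}

# oracle: naive literal-convention silhouette by explicit loops
oracle_silhouette <- function(D, labels) {
  n <- nrow(D)
  cl <- sort(unique(labels))
  s <- numeric(n)
  for (i in seq_len(n)) {
    k <- labels[i]
    own <- which(labels == k)
    a <- sum(D[i, own]) / length(own)
    b <- Inf
    for (l in setdiff(cl, k)) {
      mem <- which(labels == l)
      b <- min(b, sum(D[i, mem]) / length(mem))
    }
    s[i] <- if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }
  s
}

# connectivity check for the union-kNN graph by exhaustive BFS (no igraph)
oracle_connected <- function(A) {
  A <- as.matrix(A) > 0
  n <- nrow(A)
  seen <- logical(n)
  queue <- 1L
  seen[1] <- TRUE
  while (length(queue) > 0) {
    v <- queue[1]; queue <- queue[-1]
    nb <- which(A[v, ] & !seen)
    seen[nb] <- TRUE
    queue <- c(queue, nb)
  }
  all(seen)
}

expect_symmetric <- function(M, tol = 1e-10) {
  expect_lt(max(abs(as.matrix(M) - t(as.matrix(M)))), tol)
}
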