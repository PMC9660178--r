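#' Synthetic benchmark datasets
#'
#' Four labelled generators emulating the structures that trip up
#' distance-based embeddings: severely imbalanced Gaussian clusters, noisy
#' one-dimensional curves, hierarchically arranged Gaussian clusters, and a
#' high-dimensional branching trajectory. Every generator is deterministic
#' given `seed`, records the exact generative truth (means, curves, branch
#' endpoints, noiseless positions) so tests can verify geometry, and accepts
#' overrides of the frozen defaults.
#'
#' @param seed integer seed; the same seed reproduces the draw bit-exactly.
#' @param n_major,n_minor cluster sizes for the imbalanced case.
#' @param sep distance between the two Gaussian means (imbalanced case).
#' @param sd within-cluster standard deviation (isotropic).
#' @return A `sasne_dataset`: list with `data` (numeric matrix, rows =
#'   samples), `labels` (integer cluster/branch ids), `truth` (generative
#'   parameters and noiseless positions), `seed`, and `name`.
#' @examples
#' ds <- gen_imbalanced(seed = 1)
#' table(ds$labels)
#' @name synthetic_data
NULL

new_sasne_dataset <- function(data, labels, truth, seed, name) {
  stopifnot(nrow(data) == length(labels))
  structure(
    list(
      data = data, labels = as.integer(labels), truth = truth,
      seed = as.integer(seed), name = name
    ),
    class = "sasne_dataset"
  )
}

#' @export
print.sasne_dataset <- function(x, ...) {
  cat(sprintf(
    "<sasne_dataset '%s'> %d samples x %d features, %d labels, seed %d\n",
    x$name, nrow(x$data), ncol(x$data), length(unique(x$labels)), x$seed
  ))
  invisible(x)
}

#' Convert a synthetic dataset to a tibble
#'
#' @param x a `sasne_dataset`.
#' @param ... unused.
#' @return tibble with one `dim*` column per feature and a `label` column.
#' @importFrom tibble as_tibble
#' @exportS3Method
as_tibble.sasne_dataset <- function(x, ...) {
  out <- tibble::as_tibble(as.data.frame(x$data), .name_repair = "minimal")
  names(out) <- paste0("dim", seq_len(ncol(x$data)))
  out$label <- x$labels
  out
}

#' @rdname synthetic_data
#' @export
gen_imbalanced <- function(seed = 1, n_major = 1000, n_minor = 50,
                           sep = 5, sd = 1) {
  mean_major <- c(0, 0, 0)
  mean_minor <- c(sep, 0, 0)
  data <- withr::with_seed(seed, {
    rbind(
      matrix(rnorm(n_major * 3, sd = sd), n_major, 3, byrow = TRUE) +
        matrix(mean_major, n_major, 3, byrow = TRUE),
      matrix(rnorm(n_minor * 3, sd = sd), n_minor, 3, byrow = TRUE) +
        matrix(mean_minor, n_minor, 3, byrow = TRUE)
    )
  })
  new_sasne_dataset(
    data, rep(1:2, c(n_major, n_minor)),
    truth = list(
      means = rbind(mean_major, mean_minor), sd = sd,
      sizes = c(n_major, n_minor)
    ),
    seed, "imbalanced"
  )
}

# Parametric curves for the nonlinear benchmark: two radius-5 half circles in
# orthogonal planes whose endpoints leave a gap of about 2, so the noiseless
# curves never come closer than ~6x the default noise scale.
.nonlinear_curve <- function(t, id, radius = 5, offset = 2) {
  if (id == 1L) {
    cbind(radius * cos(t), radius * sin(t), 0)               # xy-plane, y >= 0
  } else {
    cbind(offset + radius * cos(t), 0, radius * sin(t))      # xz-plane, z <= 0
  }
}

#' @rdname synthetic_data
#' @param n_per_curve points per curve (nonlinear case).
#' @param noise_sd isotropic Gaussian noise scale.
#' @export
gen_nonlinear <- function(seed = 1, n_per_curve = 400, noise_sd = 0.3) {
  gen <- withr::with_seed(seed, {
    t1 <- sort(runif(n_per_curve, 0, pi))
    t2 <- sort(runif(n_per_curve, pi, 2 * pi))
    noise <- matrix(rnorm(2 * n_per_curve * 3, sd = noise_sd),
                    2 * n_per_curve, 3)
    list(t1 = t1, t2 = t2, noise = noise)
  })
  clean <- rbind(
    .nonlinear_curve(gen$t1, 1L),
    .nonlinear_curve(gen$t2, 2L)
  )
  new_sasne_dataset(
    clean + gen$noise, rep(1:2, each = n_per_curve),
    truth = list(
      params = c(gen$t1, gen$t2), clean = clean, noise_sd = noise_sd,
      radius = 5, offset = 2
    ),
    seed, "nonlinear"
  )
}

#' @rdname synthetic_data
#' @param n_per_cluster points per cluster (hierarchical case).
#' @export
gen_hierarchical <- function(seed = 1, n_per_cluster = 100, sd = 1) {
  # two super-clusters of three sub-clusters each; within-group mean-mean
  # distances (<= 6) are strictly below every between-group distance (>= 12)
  group_centers <- rbind(c(0, 0, 0), c(12, 0, 0))
  offsets <- rbind(c(0, 3, 0), c(0, -3, 0), c(0, 0, 3))
  means <- rbind(
    sweep(offsets, 2, group_centers[1, ], "+"),
    sweep(offsets, 2, group_centers[2, ], "+")
  )
  data <- withr::with_seed(seed, {
    do.call(rbind, lapply(1:6, function(k) {
      matrix(rnorm(n_per_cluster * 3, sd = sd), n_per_cluster, 3) +
        matrix(means[k, ], n_per_cluster, 3, byrow = TRUE)
    }))
  })
  new_sasne_dataset(
    data, rep(1:6, each = n_per_cluster),
    truth = list(
      means = means, sd = sd, group = rep(1:2, each = 3),
      mean_dist = as.matrix(dist(means))
    ),
    seed, "hierarchical"
  )
}

# Branch layout for the tree benchmark: a recursive branching structure in
# the style of developmental-trajectory benchmarks. Segment 1 grows from
# the origin along the first coordinate; every later segment starts at the
# endpoint of a (seeded) randomly chosen earlier segment and extends along
# its own coordinate, so the tree branches off in ten orthogonal directions
# with no single dominant path. Lives in the first 10 of 60 dimensions
# before noise; segment lengths are large relative to the isotropic noise
# radius (~ sqrt(60) * sd) so the manifold, not the noise, sets the
# geometry.
.tree_segments <- function(parents, dim = 60, branch_len = 20) {
  segs <- vector("list", 10)
  segs[[1]] <- list(
    start = rep(0, dim),
    end = replace(rep(0, dim), 1, branch_len),
    parent = 0L
  )
  for (j in 2:10) {
    s <- segs[[parents[j - 1]]]$end
    e <- s; e[j] <- e[j] + branch_len
    segs[[j]] <- list(start = s, end = e, parent = parents[j - 1])
  }
  segs
}

#' @rdname synthetic_data
#' @param n_per_branch points per tree segment (10 segments).
#' @param dim ambient dimension of the tree benchmark.
#' @export
gen_tree <- function(seed = 1, n_per_branch = 144, dim = 60, noise_sd = 0.5) {
  n <- 10L * n_per_branch
  gen <- withr::with_seed(seed, {
    list(
      parents = vapply(2:10, function(j) sample.int(j - 1L, 1), integer(1)),
      pos = runif(n),
      noise = matrix(rnorm(n * dim, sd = noise_sd), n, dim)
    )
  })
  segs <- .tree_segments(gen$parents, dim)
  clean <- matrix(0, n, dim)
  labels <- integer(n)
  arclen <- numeric(n)
  for (b in 1:10) {
    idx <- ((b - 1) * n_per_branch + 1):(b * n_per_branch)
    t <- gen$pos[idx]
    s <- segs[[b]]$start; e <- segs[[b]]$end
    clean[idx, ] <- outer(1 - t, s) + outer(t, e)
    labels[idx] <- b
    arclen[idx] <- t * sqrt(sum((e - s)^2))
  }
  new_sasne_dataset(
    clean + gen$noise, labels,
    truth = list(
      segments = segs, clean = clean, arclength = arclen,
      noise_sd = noise_sd
    ),
    seed, "tree"
  )
}
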