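#' Default perplexity: 90 percent of the number of points
#'
#' With a globally valid distance measure such as the biharmonic distance,
#' the Gaussian kernel can safely cover almost all other points, so the
#' perplexity defaults to `0.9 * n`, capped at `n - 2` so the entropy
#' bisection always brackets (perplexity equal to n would require an
#' infinite bandwidth). Leaving out the last 10 percent also keeps outliers
#' from inflating kernel widths.
#'
#' @param n number of samples (`n >= 4`).
#' @return numeric perplexity.
#' @examples
#' default_perplexity(1000)  # 900
#' @export
default_perplexity <- function(n) {
  if (n < 4) stop("need at least 4 samples", call. = FALSE)
  min(0.9 * n, n - 2)
}

#' Gaussian input affinities at fixed perplexity
#'
#' Converts a distance matrix into the symmetric joint probabilities used by
#' t-SNE. For each point i a bandwidth `sigma_i` is found by bisection so
#' that the conditional distribution `p_{j|i} proportional to
#' exp(-d_ij^2 / (2 sigma_i^2))` has Shannon entropy `H` with
#' `2^H = perplexity`, i.e. the kernel covers an effective number of
#' neighbors equal to the perplexity. Conditionals are then symmetrised:
#' `p_ij = (p_{j|i} + p_{i|j}) / (2n)`, which sums to 1 over all pairs.
#' Rows whose distances are all equal have perplexity-independent entropy
#' and yield the uniform conditional.
#'
#' @param D symmetric distance matrix (any distance kind).
#' @param perplexity target effective neighbor count, in `[2, n - 1]` (the
#'   upper end is the infinite-bandwidth limit; the default pipeline stays at
#'   `n - 2` or below so the bisection brackets strictly).
#' @param tol convergence tolerance on `log(perplexity)`.
#' @param max_iter bisection iteration cap per point.
#' @return a `sasne_affinity`: list with `p` (symmetric joint matrix),
#'   `perplexity`, `sigmas`, and `achieved` (realised per-point perplexity).
#' @export
conditional_affinities <- function(D, perplexity, tol = 1e-7,
                                   max_iter = 200) {
  D <- check_dist_matrix(D)
  n <- nrow(D)
  if (perplexity < 2 || perplexity > n - 1) {
    # perplexity n - 1 is the infinite-bandwidth limit (uniform conditionals);
    # anything above it is unattainable for any bandwidth
    stop(sprintf("perplexity must be in [2, %d], got %s", n - 1, perplexity),
         call. = FALSE)
  }
  target <- log(perplexity)
  P <- matrix(0, n, n)
  sigmas <- numeric(n)
  achieved <- numeric(n)
  for (i in seq_len(n)) {
    d2 <- D[i, -i]^2
    if (diff(range(d2)) < .Machine$double.eps * max(1, max(d2))) {
      # degenerate row: entropy is bandwidth-independent, use uniform
      p <- rep(1 / (n - 1), n - 1)
      beta <- 0
      H <- log(n - 1)
    } else {
      d2 <- d2 / max(d2)  # scale invariance: only relative distances matter
      beta <- 1
      beta_lo <- -Inf
      beta_hi <- Inf
      for (it in seq_len(max_iter)) {
        w <- exp(-beta * d2)
        s <- sum(w)
        H <- log(s) + beta * sum(d2 * w) / s
        if (abs(H - target) < tol) break
        if (H > target) {  # entropy too high: narrow the kernel
          beta_lo <- beta
          beta <- if (is.finite(beta_hi)) (beta + beta_hi) / 2 else beta * 2
        } else {
          beta_hi <- beta
          beta <- if (is.finite(beta_lo)) (beta + beta_lo) / 2 else beta / 2
        }
      }
      p <- exp(-beta * d2)
      p <- p / sum(p)
    }
    P[i, -i] <- p
    sigmas[i] <- if (beta > 0) sqrt(max(D[i, -i])^2 / (2 * beta)) else Inf
    achieved[i] <- exp(H)
  }
  structure(
    list(p = (P + t(P)) / (2 * n), perplexity = perplexity,
         sigmas = sigmas, achieved = achieved),
    class = "sasne_affinity"
  )
}

#' Student-t output affinities
#'
#' Heavy-tailed kernel over the 2D embedding:
#' `q_ij = (1 + ||y_i - y_j||^2)^-1 / Z` with Z normalising over all
#' ordered pairs. The heavy tail lets moderate input distances map to large
#' output distances, countering the crowding problem.
#'
#' @param coords n x 2 matrix of embedding coordinates.
#' @return list with `q` (joint probabilities, zero diagonal), `Z`
#'   (normaliser), and `w` (unnormalised kernel matrix).
#' @export
low_dim_affinities <- function(coords) {
  coords <- as.matrix(coords)
  stopifnot(all(is.finite(coords)))
  sq <- rowSums(coords^2)
  d2 <- outer(sq, sq, "+") - 2 * tcrossprod(coords)
  d2[d2 < 0] <- 0
  w <- 1 / (1 + d2)
  diag(w) <- 0
  Z <- sum(w)
  list(q = w / Z, Z = Z, w = w)
}

#' Kullback-Leibler divergence between affinity distributions
#'
#' `KL(P || Q) = sum_ij p_ij log(p_ij / q_ij)` over pairs, with the
#' convention that terms with `p_ij = 0` contribute zero.
#'
#' @param p a `sasne_affinity` or a joint probability matrix.
#' @param q joint probability matrix of the same dimension.
#' @return nonnegative scalar, zero iff the distributions coincide.
#' @export
kl_divergence <- function(p, q) {
  P <- if (inherits(p, "sasne_affinity")) p$p else as.matrix(p)
  q <- as.matrix(q)
  pos <- P > 0
  if (any(q[pos] == 0)) {
    stop("q is zero where p is positive; KL divergence undefined",
         call. = FALSE)
  }
  sum(P[pos] * log(P[pos] / q[pos]))
}

#' Gradient-descent optimisation of the t-SNE cost
#'
#' Minimises `KL(P || Q)` over 2D coordinates with the standard optimiser:
#' momentum gradient descent with per-coordinate adaptive gains and an early
#' exaggeration phase in which the input affinities are multiplied by a
#' constant factor so that clusters can separate before fine structure is
#' resolved. Initial coordinates are drawn from an isotropic Gaussian with
#' standard deviation 1e-4; given the same seed the run is bit-identical.
#'
#' @param p a `sasne_affinity` (or joint probability matrix).
#' @param iters number of gradient iterations.
#' @param lr learning rate; default `max(n / 12, 50)`.
#' @param seed integer seed for the initial coordinates.
#' @param exaggeration early exaggeration factor.
#' @param exaggeration_iter iteration at which exaggeration ends (clamped to
#'   `iters`).
#' @param momentum momentum before and after `momentum_switch`.
#' @param momentum_switch iteration at which momentum increases.
#' @param trace_every record the KL cost every this many iterations
#'   (default 1, a full per-iteration trace; the final iteration is always
#'   recorded, intermediate untraced entries are `NA`). The trace never
#'   affects the coordinates.
#' @return a `sasne_embedding`: list with `coords` (n x 2), `kl_trace`
#'   (KL divergence against the unexaggerated P at every traced iteration),
#'   `seed`, and `params`.
#' @export
tsne_optimize <- function(p, iters = 1000, lr = NULL, seed = 1,
                          exaggeration = 12, exaggeration_iter = 250,
                          momentum = c(0.5, 0.8), momentum_switch = 250,
                          trace_every = 1) {
  P <- if (inherits(p, "sasne_affinity")) p$p else as.matrix(p)
  n <- nrow(P)
  stopifnot(iters >= 1, n >= 2)
  if (is.null(lr)) lr <- max(n / 12, 50)
  ex_end <- min(exaggeration_iter, iters)
  Y <- withr::with_seed(seed, matrix(rnorm(2 * n, sd = 1e-4), n, 2))
  gains <- matrix(1, n, 2)
  update <- matrix(0, n, 2)
  kl_trace <- rep(NA_real_, iters)
  pos <- P > 0
  Ppos <- P[pos]
  p_logp <- sum(Ppos * log(Ppos))
  for (t in seq_len(iters)) {
    Pt <- if (t <= ex_end) exaggeration else 1
    sq <- rowSums(Y^2)
    d2 <- outer(sq, sq, "+") - 2 * tcrossprod(Y)
    d2[d2 < 0] <- 0
    w <- 1 / (1 + d2)
    diag(w) <- 0
    Z <- sum(w)
    Q <- w / Z
    M <- (Pt * P - Q) * w
    grad <- 4 * (rowSums(M) * Y - M %*% Y)
    flip <- sign(grad) != sign(update)
    gains <- pmax(ifelse(flip, gains + 0.2, gains * 0.8), 0.01)
    mom <- if (t <= momentum_switch) momentum[1] else momentum[2]
    update <- mom * update - lr * gains * grad
    Y <- Y + update
    Y <- sweep(Y, 2, colMeans(Y))
    if (!all(is.finite(Y))) {
      stop(sprintf(
        "optimisation diverged at iteration %d (non-finite coordinates); try a smaller learning rate",
        t
      ), call. = FALSE)
    }
    if (t %% trace_every == 0 || t == iters) {
      kl_trace[t] <- p_logp - sum(Ppos * log(pmax(Q[pos], 1e-12)))
    }
  }
  structure(
    list(
      coords = Y, kl_trace = kl_trace, seed = as.integer(seed),
      params = list(
        perplexity = if (inherits(p, "sasne_affinity")) p$perplexity else NA,
        iters = iters, lr = lr, exaggeration = exaggeration,
        exaggeration_iter = ex_end, momentum = momentum,
        momentum_switch = momentum_switch
      ),
      n = n
    ),
    class = "sasne_embedding"
  )
}

#' t-SNE on a precomputed distance matrix
#'
#' Runs the full t-SNE core — perplexity-calibrated Gaussian affinities
#' followed by gradient optimisation — on any distance matrix. This is the
#' Euclidean-distance baseline when fed [euclidean_distances()], and the
#' shape-aware embedding when fed [biharmonic_distances()].
#'
#' @param D symmetric distance matrix.
#' @param perplexity effective neighbor count; defaults to
#'   [default_perplexity()] of the sample count.
#' @inheritParams tsne_optimize
#' @param ... further arguments passed to [tsne_optimize()].
#' @return a `sasne_embedding` (with the affinities in `$affinity`).
#' @export
tsne_embed <- function(D, perplexity = NULL, iters = 1000, seed = 1, ...) {
  D <- check_dist_matrix(D)
  n <- nrow(D)
  if (is.null(perplexity)) perplexity <- default_perplexity(n)
  aff <- conditional_affinities(D, perplexity)
  emb <- tsne_optimize(aff, iters = iters, seed = seed, ...)
  emb$affinity <- aff
  emb$distance_kind <- attr(D, "kind") %||% "precomputed"
  emb
}

#' Shape-aware stochastic neighbor embedding
#'
#' The full pipeline: build the minimally-connected kNN similarity graph
#' ([adaptive_graph()]), compute biharmonic distances from the Laplacian
#' spectrum ([biharmonic_distances()]), and embed them with the t-SNE core
#' at a perplexity of 90 percent of the number of points. Because the
#' biharmonic distance is a globally valid, shape-aware metric, the large
#' perplexity preserves global and hierarchical organisation rather than
#' producing spurious local clusters.
#'
#' @param x a data matrix / data frame / `sasne_dataset`, or an
#'   already-built connected `sasne_graph`.
#' @param perplexity effective neighbor count; default 90 percent of n.
#' @param k_cap recursion cap for [adaptive_graph()].
#' @param iters gradient iterations.
#' @param seed integer seed (initial coordinates).
#' @param keep_intermediates store the graph and distance matrix on the
#'   result for inspection.
#' @param ... passed on to [tsne_optimize()].
#' @return a `sasne_embedding`; with `keep_intermediates = TRUE` it also
#'   carries `$graph` and `$distances`.
#' @examples
#' ds <- gen_hierarchical(seed = 1, n_per_cluster = 20)
#' emb <- sasne(ds, iters = 50, seed = 1)
#' head(tidy(emb))
#' @export
sasne <- function(x, perplexity = NULL, k_cap = 5, iters = 1000, seed = 1,
                  keep_intermediates = TRUE, ...) {
  graph <- if (inherits(x, "sasne_graph")) x else adaptive_graph(x, k_cap = k_cap)
  if (!graph$connected) {
    stop("graph is not connected; biharmonic distances are undefined",
         call. = FALSE)
  }
  B <- biharmonic_distances(graph)
  emb <- tsne_embed(B, perplexity = perplexity, iters = iters, seed = seed, ...)
  emb$distance_kind <- "biharmonic"
  emb$k_used <- graph$k_used
  if (keep_intermediates) {
    emb$graph <- graph
    emb$distances <- B
  }
  emb
}

#' @export
print.sasne_embedding <- function(x, ...) {
  cat(sprintf(
    "<sasne_embedding> %d points, %s distances, perplexity %.6g, %d iterations, final KL %.3g\n",
    x$n, x$distance_kind %||% "unspecified",
    x$params$perplexity, x$params$iters, tail(x$kl_trace, 1)
  ))
  invisible(x)
}

#' @exportS3Method
tidy.sasne_embedding <- function(x, ...) {
  tibble::tibble(
    sample = seq_len(x$n),
    y1 = x$coords[, 1],
    y2 = x$coords[, 2]
  )
}

#' @exportS3Method
glance.sasne_embedding <- function(x, ...) {
  tibble::tibble(
    n = x$n,
    perplexity = x$params$perplexity,
    iters = x$params$iters,
    k_used = x$k_used %||% NA_integer_,
    distance_kind = x$distance_kind %||% "unspecified",
    final_kl = tail(x$kl_trace, 1),
    seed = x$seed
  )
}

#' @exportS3Method
autoplot.sasne_embedding <- function(object, labels = NULL, ...) {
  df <- tidy(object)
  if (!is.null(labels)) df$label <- factor(labels)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$y1, y = .data$y2)) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "y1", y = "y2") +
    ggplot2::theme_minimal()
  if (is.null(labels)) {
    p + ggplot2::geom_point(size = 0.8, alpha = 0.8)
  } else {
    p + ggplot2::geom_point(ggplot2::aes(colour = .data$label),
                            size = 0.8, alpha = 0.8)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a
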