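#' Neighbor rank matrix of a distance matrix
#'
#' For every point i, ranks all other points by distance: `R[i, j] = r` when
#' j is the r-th closest point to i (self excluded, so each row holds a
#' permutation of `1..n-1` off the diagonal). Ties are broken by ascending
#' sample index with a stable sort, and the identical rule applies to
#' high- and low-dimensional matrices so that identical inputs give
#' identical ranks bit-exactly.
#'
#' @param D symmetric distance matrix, or a `sasne_embedding` (its 2D
#'   Euclidean distances are ranked).
#' @return n x n integer matrix with zero diagonal.
#' @export
rank_matrix <- function(D) {
  if (inherits(D, "sasne_embedding")) D <- euclidean_distances(D$coords)
  D <- check_dist_matrix(D)
  n <- nrow(D)
  R <- matrix(0L, n, n)
  for (i in seq_len(n)) {
    others <- setdiff(seq_len(n), i)
    ord <- others[order(D[i, others], others)]
    R[i, ord] <- seq_len(n - 1L)
  }
  R
}

#' Mean absolute rank error between two rank matrices
#'
#' Point-wise quality of rank preservation between a high-dimensional and a
#' low-dimensional rank matrix:
#' `rbar_i = (1 / (n-1)) * sum_{j != i} |R_hd[i,j] - R_ld[i,j]| / (n-1)`,
#' and the overall average rank error `Rbar = mean_i rbar_i`. Both lie in
#' `[0, 1]`, with 0 for perfect rank preservation. (The normalisation bound
#' of 1 is attained per pair, not per mean: a full rank reversal yields a
#' point-wise value of about 1/2.)
#'
#' @param ranks_hd,ranks_ld integer rank matrices from [rank_matrix()], or
#'   objects coercible by it (distance matrices, embeddings).
#' @return list with `per_point` (length-n vector) and `overall` (scalar).
#' @export
mare <- function(ranks_hd, ranks_ld) {
  Rx <- .as_ranks(ranks_hd)
  Ry <- .as_ranks(ranks_ld)
  if (!all(dim(Rx) == dim(Ry))) {
    stop("rank matrices must have identical dimensions", call. = FALSE)
  }
  n <- nrow(Rx)
  per_point <- rowSums(abs(Rx - Ry)) / (n - 1)^2
  list(per_point = per_point, overall = mean(per_point))
}

.as_ranks <- function(x) {
  if (inherits(x, "sasne_embedding") || inherits(x, "dist")) {
    return(rank_matrix(x))
  }
  stopifnot(is.matrix(x))
  if (.looks_like_ranks(x)) x else rank_matrix(x)
}

# a rank matrix has zero diagonal and every row a permutation of 1..n-1
.looks_like_ranks <- function(x) {
  n <- nrow(x)
  if (n != ncol(x) || any(diag(x) != 0) || any(x != round(x))) return(FALSE)
  target <- seq_len(n - 1L)
  for (i in seq_len(n)) {
    if (!identical(as.integer(sort(x[i, -i])), target)) return(FALSE)
  }
  TRUE
}

#' Rank residual plot histogram
#'
#' Two-dimensional histogram of rank residuals: every ordered pair (i, j)
#' deposits one count at abscissa `R_hd[i,j] / (n-1)` (normalised original
#' rank, in (0, 1]) and ordinate `(R_hd[i,j] - R_ld[i,j]) / (n-1)`
#' (normalised residual, strictly inside (-1, 1)). Perfect rank
#' preservation concentrates all mass on the horizontal zero line; the left
#' and right sides of the abscissa expose local- and global-scale
#' distortion respectively. The mean-absolute-rank-error summaries are
#' attached.
#'
#' @inheritParams mare
#' @param n_bins number of bins along each axis (default 100).
#' @return a `sasne_rrp`: list with `bins` (count matrix, rows = residual
#'   bins), `x_edges`, `y_edges`, `mare_per_point`, `average_rank_error`,
#'   and `n`.
#' @export
rrp <- function(ranks_hd, ranks_ld, n_bins = 100) {
  stopifnot(n_bins >= 2)
  Rx <- .as_ranks(ranks_hd)
  Ry <- .as_ranks(ranks_ld)
  n <- nrow(Rx)
  off <- row(Rx) != col(Rx)
  x <- Rx[off] / (n - 1)
  y <- (Rx[off] - Ry[off]) / (n - 1)
  x_edges <- seq(0, 1, length.out = n_bins + 1)
  y_edges <- seq(-1, 1, length.out = n_bins + 1)
  xi <- pmin(pmax(findInterval(x, x_edges, left.open = TRUE), 1L), n_bins)
  yi <- pmin(findInterval(y, y_edges), n_bins)
  bins <- matrix(0L, n_bins, n_bins)
  tab <- table(factor(yi, levels = seq_len(n_bins)),
               factor(xi, levels = seq_len(n_bins)))
  bins[] <- as.integer(tab)
  m <- mare(Rx, Ry)
  structure(
    list(bins = bins, x_edges = x_edges, y_edges = y_edges,
         mare_per_point = m$per_point, average_rank_error = m$overall,
         n = n),
    class = "sasne_rrp"
  )
}

#' @export
print.sasne_rrp <- function(x, ...) {
  cat(sprintf(
    "<sasne_rrp> %d points, %d x %d bins, average rank error %.4f\n",
    x$n, nrow(x$bins), ncol(x$bins), x$average_rank_error
  ))
  invisible(x)
}

#' Silhouette statistics under an arbitrary distance
#'
#' Point-wise silhouette values for labelled data under any distance
#' matrix: cohesion `a_i` is the mean distance from point i to all members
#' of its own cluster (self included, divisor `N_k` — the formula is applied
#' literally; set `convention = "rousseeuw"` for the classical self-excluded
#' `N_k - 1` form), separation `b_i` is the mean distance to the nearest
#' other cluster, and `s_i = (b_i - a_i) / max(a_i, b_i)`, which lies in
#' `[-1, 1]`. When `max(a_i, b_i) = 0` (fully coincident points) the value
#' is defined as 0. Cluster scores are member means and the overall
#' coefficient is the unweighted mean over clusters.
#'
#' @param D symmetric distance matrix (Euclidean, biharmonic, ...).
#' @param labels cluster assignment, one per sample; at least two distinct
#'   clusters.
#' @param convention `"literal"` (self-inclusive cohesion, default) or
#'   `"rousseeuw"` (self-excluded; singletons get `s_i = 0`).
#' @return a `sasne_silhouette`: list with `point_values`, `cluster_scores`
#'   (named by cluster), `coefficient`, `distance_kind`, and `convention`.
#' @export
silhouette_report <- function(D, labels, convention = c("literal", "rousseeuw")) {
  convention <- match.arg(convention)
  kind <- attr(D, "kind") %||% "precomputed"
  D <- check_dist_matrix(D)
  n <- nrow(D)
  if (length(labels) != n) stop("labels must match the matrix size", call. = FALSE)
  labels <- as.vector(labels)
  cl <- sort(unique(labels))
  if (length(cl) < 2) stop("need at least two clusters", call. = FALSE)
  members <- lapply(cl, function(k) which(labels == k))
  # point-to-cluster mean distances, n x K
  pc <- vapply(members, function(idx) rowSums(D[, idx, drop = FALSE]) / length(idx),
               numeric(n))
  s <- numeric(n)
  for (i in seq_len(n)) {
    k <- match(labels[i], cl)
    nk <- length(members[[k]])
    if (convention == "literal") {
      a <- pc[i, k]
    } else {
      if (nk == 1L) { s[i] <- 0; next }
      a <- (pc[i, k] * nk) / (nk - 1)  # remove the zero self-term
    }
    b <- min(pc[i, -k])
    s[i] <- if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }
  cluster_scores <- vapply(seq_along(cl),
                           function(k) mean(s[members[[k]]]), numeric(1))
  names(cluster_scores) <- as.character(cl)
  structure(
    list(point_values = s, cluster_scores = cluster_scores,
         coefficient = mean(cluster_scores), distance_kind = kind,
         convention = convention, labels = labels),
    class = "sasne_silhouette"
  )
}

#' @export
print.sasne_silhouette <- function(x, ...) {
  cat(sprintf(
    "<sasne_silhouette> %d points, %d clusters (%s distances, %s convention)\n",
    length(x$point_values), length(x$cluster_scores), x$distance_kind,
    x$convention
  ))
  cat("  coefficient:", format(x$coefficient, digits = 4), "\n")
  invisible(x)
}

#' @exportS3Method
tidy.sasne_silhouette <- function(x, ...) {
  tibble::tibble(
    cluster = names(x$cluster_scores),
    score = unname(x$cluster_scores)
  )
}

#' @exportS3Method
glance.sasne_silhouette <- function(x, ...) {
  tibble::tibble(
    n = length(x$point_values),
    n_clusters = length(x$cluster_scores),
    coefficient = x$coefficient,
    distance_kind = x$distance_kind,
    convention = x$convention
  )
}

#' Tabulate validation results across methods and datasets
#'
#' Collects rank-error and silhouette summaries from several runs into one
#' table for side-by-side comparison.
#'
#' @param reports named list; each element is a list that may hold `rrp`
#'   (a `sasne_rrp`) and/or `silhouette` (a `sasne_silhouette`). Missing
#'   slots yield `NA`, not zero.
#' @return tibble with columns `name`, `avg_rank_error`, `silhouette`.
#' @export
compare_runs <- function(reports) {
  stopifnot(length(reports) >= 1, !is.null(names(reports)))
  dplyr::bind_rows(lapply(names(reports), function(nm) {
    r <- reports[[nm]]
    tibble::tibble(
      name = nm,
      avg_rank_error = if (!is.null(r$rrp)) r$rrp$average_rank_error else NA_real_,
      silhouette = if (!is.null(r$silhouette)) r$silhouette$coefficient else NA_real_
    )
  }))
}

#' Plot a rank residual histogram
#'
#' Relative-density heat map of the rank residual plot; cells with no mass
#' (unreachable rank combinations) are left white.
#'
#' @param x a `sasne_rrp`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
plot_rrp <- function(x, ...) {
  stopifnot(inherits(x, "sasne_rrp"))
  xc <- (head(x$x_edges, -1) + tail(x$x_edges, -1)) / 2
  yc <- (head(x$y_edges, -1) + tail(x$y_edges, -1)) / 2
  df <- expand.grid(residual = yc, rank = xc)
  df$density <- as.vector(x$bins) / sum(x$bins)
  df <- df[df$density > 0, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rank, y = .data$residual,
                                   fill = .data$density)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(trans = "sqrt") +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(-1, 1)) +
    ggplot2::labs(
      x = "normalised input rank", y = "normalised rank residual",
      fill = "relative\ndensity",
      title = sprintf("average rank error %.3f", x$average_rank_error)
    ) +
    ggplot2::theme_minimal()
}

#' @exportS3Method
autoplot.sasne_rrp <- function(object, ...) plot_rrp(object, ...)

#' Plot silhouette scores per cluster
#'
#' Bar plot of cluster-wise silhouette scores with the overall coefficient
#' as a dashed line.
#'
#' @param x a `sasne_silhouette`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
plot_silhouette <- function(x, ...) {
  stopifnot(inherits(x, "sasne_silhouette"))
  df <- tidy(x)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$cluster, y = .data$score)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = x$coefficient, linetype = "dashed") +
    ggplot2::labs(x = "cluster", y = "silhouette score",
                  title = sprintf("silhouette coefficient %.3f", x$coefficient)) +
    ggplot2::theme_minimal()
}

#' @exportS3Method
autoplot.sasne_silhouette <- function(object, ...) plot_silhouette(object, ...)
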