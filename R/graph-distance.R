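#' Graph Laplacian of a weighted graph
#'
#' Combinatorial (unnormalised) Laplacian `L = D - W` with
#' `D = diag(rowSums(W))`. Its null space is spanned by the indicator
#' vectors of the connected components; for a connected graph the single
#' null eigenvector is constant.
#'
#' @param graph a `sasne_graph`, or a symmetric nonnegative weight matrix.
#' @return dense symmetric n x n matrix with zero row sums.
#' @export
graph_laplacian <- function(graph) {
  W <- if (inherits(graph, "sasne_graph")) graph$weights else graph
  W <- as.matrix(W)
  if (max(abs(W - t(W))) > 1e-12 * max(1, max(abs(W)))) {
    stop("weight matrix must be symmetric", call. = FALSE)
  }
  if (any(W < 0)) stop("weight matrix must be nonnegative", call. = FALSE)
  diag(W) <- 0
  diag(rowSums(W)) - W
}

#' Eigendecomposition of a graph Laplacian
#'
#' Full symmetric eigendecomposition with eigenvalues in nondecreasing
#' order. Eigenvalues below `zero_tol = n * eps * lambda_max` are flagged as
#' numerically null; a connected graph must yield exactly one such
#' eigenvalue, and any other count is reported as an error rather than
#' silently repaired, since it signals numerically broken connectivity.
#'
#' @param L dense symmetric Laplacian matrix.
#' @param connected whether the underlying graph is known to be connected.
#' @return a `sasne_spectrum`: list with `values` (ascending eigenvalues),
#'   `vectors` (orthonormal columns), `zero_tol`, and `null_idx` (indices of
#'   null eigenvalues).
#' @export
laplacian_spectrum <- function(L, connected = TRUE) {
  L <- as.matrix(L)
  if (max(abs(L - t(L))) > 1e-8 * max(1, max(abs(L)))) {
    stop("Laplacian must be symmetric", call. = FALSE)
  }
  e <- eigen((L + t(L)) / 2, symmetric = TRUE)
  ord <- rev(seq_along(e$values))  # eigen() returns decreasing order
  values <- e$values[ord]
  vectors <- e$vectors[, ord, drop = FALSE]
  lam_max <- max(abs(values), 0)
  zero_tol <- nrow(L) * .Machine$double.eps * max(lam_max, 1)
  null_idx <- which(abs(values) < zero_tol)
  if (length(null_idx) == 0) null_idx <- 1L  # lambda_1 is null by theory
  if (connected && length(null_idx) != 1L) {
    stop(sprintf(
      "connected graph must have exactly one null eigenvalue, found %d (tol %.3g)",
      length(null_idx), zero_tol
    ), call. = FALSE)
  }
  structure(
    list(values = values, vectors = vectors, zero_tol = zero_tol,
         null_idx = null_idx),
    class = "sasne_spectrum"
  )
}

# Shared spectral distance kernel: pairwise sqrt of
# sum_k weight(lambda_k) * (phi_k(i) - phi_k(j))^2 over non-null eigenpairs.
.spectral_distance <- function(spec, weight_fun) {
  keep <- setdiff(seq_along(spec$values), spec$null_idx)
  if (length(keep) == 0) stop("no non-null eigenpairs", call. = FALSE)
  A <- sweep(spec$vectors[, keep, drop = FALSE], 2,
             sqrt(weight_fun(spec$values[keep])), "*")
  sq <- rowSums(A^2)
  d2 <- outer(sq, sq, "+") - 2 * tcrossprod(A)
  d2[d2 < 0] <- 0
  D <- sqrt(d2)
  D <- (D + t(D)) / 2
  diag(D) <- 0
  D
}

.resolve_spectrum <- function(x) {
  if (inherits(x, "sasne_spectrum")) return(x)
  if (inherits(x, "sasne_graph")) {
    if (!x$connected) {
      stop("graph must be connected to define spectral distances", call. = FALSE)
    }
    return(laplacian_spectrum(graph_laplacian(x), connected = TRUE))
  }
  stop("expected a sasne_graph or sasne_spectrum", call. = FALSE)
}

#' Biharmonic distance matrix
#'
#' Spectral biharmonic distance between graph nodes:
#' `d_B(i, j)^2 = sum_{k >= 2} (phi_k(i) - phi_k(j))^2 / lambda_k^2`,
#' equivalently the quadratic form of the squared Laplacian pseudo-inverse.
#' Compared with the commute-time distance (weighting `1 / lambda_k`), the
#' steeper `1 / lambda_k^2` weighting suppresses high-frequency modes and
#' stabilises the estimation of large distances, which exaggerates
#' between-cluster separation relative to within-cluster spread.
#'
#' @param x a connected `sasne_graph` or a `sasne_spectrum`.
#' @return dense symmetric distance matrix with attribute `kind =
#'   "biharmonic"`.
#' @export
biharmonic_distances <- function(x) {
  spec <- .resolve_spectrum(x)
  structure(.spectral_distance(spec, function(l) 1 / l^2),
            kind = "biharmonic")
}

#' Commute-time distance matrix
#'
#' Spectral commute-time distance,
#' `d_C(i, j)^2 = sum_{k >= 2} (phi_k(i) - phi_k(j))^2 / lambda_k`, equal to
#' the effective resistance between nodes; computed like the biharmonic
#' distance but with `1 / lambda_k` eigenvalue weighting.
#'
#' @inheritParams biharmonic_distances
#' @return dense symmetric distance matrix with attribute `kind =
#'   "commute_time"`.
#' @export
commute_time_distances <- function(x) {
  spec <- .resolve_spectrum(x)
  structure(.spectral_distance(spec, function(l) 1 / l),
            kind = "commute_time")
}

#' Pairwise Euclidean distance matrix
#'
#' @param data numeric matrix, data frame, or `sasne_dataset`.
#' @return dense symmetric distance matrix with attribute `kind =
#'   "euclidean"`.
#' @export
euclidean_distances <- function(data) {
  x <- as_data_matrix(data)
  structure(as.matrix(dist(x)), kind = "euclidean")
}
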