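#' k-nearest-neighbor similarity graphs
#'
#' The high-dimensional data are represented by a sparse weighted graph:
#' each point is joined to its k nearest neighbors (union symmetrisation:
#' the edge i-j exists if either point lists the other) and each edge
#' carries the similarity weight `w_ij = 1 / ||x_i - x_j||^2`, the inverse
#' squared Euclidean distance. No kernel bandwidth is involved, so k is the
#' only parameter, and it is chosen in a data-driven way: the smallest k
#' that leaves the graph connected ([minimal_connected_k()]), with a
#' recursive refinement for data whose components would otherwise force a
#' large k ([adaptive_graph()]).
#'
#' @param data a numeric matrix (rows = samples), data frame, or
#'   `sasne_dataset`.
#' @param k number of neighbors per point, `1 <= k <= n - 1`.
#' @param metric distance used for the neighbor search; only `"euclidean"`
#'   is implemented.
#' @return `knn_edges()` and `adaptive_graph()` return a `sasne_graph`:
#'   list with `weights` (sparse symmetric `dgCMatrix`), `k_used`,
#'   `connected`, `component_labels`, and `n`.
#' @examples
#' x <- matrix(c(0, 1, 2), ncol = 1)
#' g <- knn_edges(x, k = 1)
#' g$connected
#' @name neighbor_graph
NULL

# Neighbor orderings per row of a dense distance matrix, self excluded,
# ties broken by ascending sample index (stable).
.neighbor_orders <- function(D) {
  n <- nrow(D)
  do.call(rbind, lapply(seq_len(n), function(i) {
    ord <- order(D[i, ], seq_len(n))
    ord[ord != i]
  }))
}

# Assemble the union-symmetrised kNN graph from precomputed orderings.
# Weight floor: squared distances below eps = 1e-12 * median nonzero squared
# kNN edge distance are clamped (coincident points would give infinite w).
.knn_graph <- function(D, orders, k) {
  n <- nrow(D)
  i <- rep(seq_len(n), each = k)
  j <- as.vector(t(orders[, seq_len(k), drop = FALSE]))
  # union symmetrisation on the pattern
  A <- Matrix::sparseMatrix(i = i, j = j, x = 1, dims = c(n, n))
  A <- A + Matrix::t(A)
  At <- methods::as(A, "TsparseMatrix")
  edge <- cbind(At@i + 1L, At@j + 1L)
  d2 <- D[edge]^2
  nz <- d2[d2 > 0]
  if (length(nz) == 0) {
    stop("all selected neighbor distances are zero; samples are coincident",
         call. = FALSE)
  }
  eps <- 1e-12 * median(nz)
  if (any(d2 < eps)) {
    warning("coincident points detected; flooring squared distances at ",
            format(eps), call. = FALSE)
    d2 <- pmax(d2, eps)
  }
  W <- Matrix::sparseMatrix(
    i = edge[, 1], j = edge[, 2], x = 1 / d2, dims = c(n, n)
  )
  comp <- igraph::components(
    igraph::graph_from_adjacency_matrix(W > 0, mode = "undirected")
  )
  structure(
    list(
      weights = W, k_used = as.integer(k),
      connected = comp$no == 1L,
      component_labels = as.integer(comp$membership), n = n
    ),
    class = "sasne_graph"
  )
}

#' @export
print.sasne_graph <- function(x, ...) {
  cat(sprintf(
    "<sasne_graph> %d nodes, %d edges, k = %d, %s\n",
    x$n, Matrix::nnzero(x$weights) / 2, x$k_used,
    if (x$connected) "connected" else
      sprintf("%d components", max(x$component_labels))
  ))
  invisible(x)
}

.dist_matrix_for <- function(data, metric) {
  metric <- match.arg(metric, "euclidean")
  x <- as_data_matrix(data)
  if (nrow(x) < 2) stop("need at least 2 samples", call. = FALSE)
  as.matrix(dist(x))
}

#' @rdname neighbor_graph
#' @export
knn_edges <- function(data, k, metric = "euclidean") {
  D <- .dist_matrix_for(data, metric)
  n <- nrow(D)
  if (k < 1 || k > n - 1) {
    stop(sprintf("k must be in [1, %d], got %s", n - 1, k), call. = FALSE)
  }
  .knn_graph(D, .neighbor_orders(D), as.integer(k))
}

#' Smallest k keeping the kNN graph connected
#'
#' Scans k upward from 1 and returns the first value for which the
#' union-symmetrised kNN graph has a single connected component. Because
#' connectivity of the union graph is monotone in k and the (n-1)NN graph is
#' complete, the scan always terminates. This k marks the neighborhood size
#' below which purely local distances no longer tie the data together;
#' typical single-component clouds yield values around 5.
#'
#' @inheritParams neighbor_graph
#' @return integer k.
#' @export
minimal_connected_k <- function(data, metric = "euclidean") {
  D <- .dist_matrix_for(data, metric)
  orders <- .neighbor_orders(D)
  .minimal_k(D, orders)
}

.minimal_k <- function(D, orders) {
  n <- nrow(D)
  for (k in seq_len(n - 1L)) {
    g <- .knn_graph(D, orders, k)
    if (g$connected) return(k)
  }
  n - 1L  # unreachable: complete graph is connected
}

#' Adaptive connected graph with recursive component refinement
#'
#' Builds the kNN graph at the minimal connected k. When that k exceeds
#' `k_cap` (data with widely separated regions force a large k), the
#' components of the (k-1)NN graph are identified, the edges of the kNN
#' graph that bridge distinct components are retained, and the procedure
#' recurses on each component separately, so that within every region the
#' neighborhood size falls back to a local scale around `k_cap` while the
#' bridges keep the whole graph connected.
#'
#' @inheritParams neighbor_graph
#' @param k_cap recursion threshold on k (default 5).
#' @export
adaptive_graph <- function(data, k_cap = 5, metric = "euclidean") {
  stopifnot(k_cap >= 1)
  D <- .dist_matrix_for(data, metric)
  W <- .adaptive_weights(D, k_cap, depth = 0L)
  comp <- igraph::components(
    igraph::graph_from_adjacency_matrix(W$weights > 0, mode = "undirected")
  )
  structure(
    list(
      weights = W$weights, k_used = W$k_top,
      connected = comp$no == 1L,
      component_labels = as.integer(comp$membership), n = nrow(D)
    ),
    class = "sasne_graph"
  )
}

.adaptive_weights <- function(D, k_cap, depth) {
  n <- nrow(D)
  if (depth > n) {
    stop("adaptive graph recursion exceeded the number of samples; ",
         "this indicates a logic fault", call. = FALSE)
  }
  orders <- .neighbor_orders(D)
  kstar <- .minimal_k(D, orders)
  gk <- .knn_graph(D, orders, kstar)
  if (kstar <= k_cap || kstar == 1L) {
    return(list(weights = gk$weights, k_top = kstar))
  }
  gkm1 <- .knn_graph(D, orders, kstar - 1L)
  memb <- gkm1$component_labels
  W <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                            dims = c(n, n))
  # bridge edges: edges of the kNN graph joining distinct (k-1)-components
  Wt <- methods::as(gk$weights, "TsparseMatrix")
  edge <- cbind(Wt@i + 1L, Wt@j + 1L)
  bridge <- edge[memb[edge[, 1]] != memb[edge[, 2]], , drop = FALSE]
  if (nrow(bridge) > 0) {
    W <- W + Matrix::sparseMatrix(
      i = bridge[, 1], j = bridge[, 2], x = gk$weights[bridge],
      dims = c(n, n)
    )
  }
  for (comp in unique(memb)) {
    idx <- which(memb == comp)
    if (length(idx) == 1L) next
    sub <- .adaptive_weights(D[idx, idx, drop = FALSE], k_cap, depth + 1L)
    W[idx, idx] <- W[idx, idx] + sub$weights
  }
  list(weights = W, k_top = kstar)
}

#' Markov transition matrix of a weighted graph
#'
#' Row-normalises the similarity matrix: `P[i, j] = w_ij / sum_k w_ik`, the
#' probability that a random walk at node i steps to node j.
#'
#' @param graph a `sasne_graph`.
#' @return a row-stochastic sparse `dgCMatrix` with the sparsity pattern of
#'   the graph weights.
#' @export
transition_matrix <- function(graph) {
  stopifnot(inherits(graph, "sasne_graph"))
  deg <- Matrix::rowSums(graph$weights)
  if (any(deg == 0)) {
    stop("graph has isolated nodes (zero-degree rows): ",
         paste(which(deg == 0), collapse = ", "), call. = FALSE)
  }
  Matrix::Diagonal(x = 1 / deg) %*% graph$weights
}
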