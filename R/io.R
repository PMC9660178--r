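#' Read a data or distance matrix from disk
#'
#' Dense matrices are read from CSV/TSV (separator auto-detected, optional
#' header); sparse count matrices from Matrix Market `.mtx` files are
#' densified, since the spectral pipeline needs dense eigendecompositions
#' anyway. Matrices tagged as distances are validated (square, symmetric
#' within `1e-8`, then symmetrised with the diagonal zeroed) and asymmetry
#' beyond tolerance is an error naming the offending entries.
#'
#' @param path file path (`.csv` / `.tsv` / `.txt` or `.mtx`).
#' @param kind `"data"` (samples x features), `"distance"` (square
#'   symmetric), or `"mtx"` (Matrix Market, treated as a data matrix).
#' @param header whether the text file has a header row (auto by default).
#' @param max_n densification guard for sparse inputs.
#' @return a numeric matrix; distance matrices carry `attr(, "kind") =
#'   "precomputed"`.
#' @export
read_matrix <- function(path, kind = c("data", "distance", "mtx"),
                        header = "auto", max_n = 20000) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (kind == "mtx" || grepl("\\.mtx$", path, ignore.case = TRUE)) {
    m <- as.matrix(Matrix::readMM(path))
    if (nrow(m) > max_n) {
      stop(sprintf("sparse input has %d rows, above the densification cap %d",
                   nrow(m), max_n), call. = FALSE)
    }
    return(m)
  }
  if (identical(header, "auto")) {
    # our own writers emit a header of 0-based indices, which looks numeric;
    # recognise an exact 0..k-1 first row as a header, not data
    first <- strsplit(readLines(path, n = 1), "[,\t;]")[[1]]
    idx_header <- length(first) > 0 &&
      all(grepl("^[0-9]+$", trimws(first))) &&
      identical(as.integer(trimws(first)), seq_along(first) - 1L)
    if (idx_header) header <- TRUE
  }
  dt <- data.table::fread(path, header = header)
  if (ncol(dt) > 0 && !is.numeric(dt[[1]])) dt <- dt[, -1]  # row-id column
  if (!all(vapply(dt, is.numeric, logical(1)))) {
    stop("non-numeric cells in ", path, call. = FALSE)
  }
  m <- as.matrix(dt)
  dimnames(m) <- NULL
  if (kind == "distance") {
    m <- check_dist_matrix(m)
    attr(m, "kind") <- "precomputed"
  }
  m
}

#' Write a dense matrix as CSV
#'
#' Full square/rectangular CSV with a header row of 0-based column indices,
#' for human inspectability at desk scale.
#'
#' @param x numeric matrix.
#' @param path output path.
#' @export
write_matrix <- function(x, path) {
  x <- as.matrix(x)
  dt <- data.table::as.data.table(x)
  names(dt) <- as.character(seq_len(ncol(x)) - 1L)
  data.table::fwrite(dt, path)
  invisible(path)
}

#' Read per-sample labels
#'
#' One label token per line; string labels are mapped to dense 0-based
#' integer ids in order of first appearance, with the mapping stored as the
#' `levels` attribute.
#'
#' @param path label file.
#' @param n expected number of samples; a count mismatch is an error.
#' @return integer vector of 0-based ids with attribute `levels`.
#' @export
read_labels <- function(path, n = NULL) {
  if (!file.exists(path)) stop("label file not found: ", path, call. = FALSE)
  raw <- trimws(readLines(path))
  raw <- raw[nzchar(raw)]
  if (!is.null(n) && length(raw) != n) {
    stop(sprintf("expected %d labels, found %d in %s", n, length(raw), path),
         call. = FALSE)
  }
  lev <- unique(raw)
  structure(match(raw, lev) - 1L, levels = lev)
}

#' Write labels, one per line
#' @param labels vector of labels.
#' @param path output path.
#' @export
write_labels <- function(labels, path) {
  writeLines(as.character(labels), path)
  invisible(path)
}

# JSON provenance sidecar next to an artifact.
write_sidecar <- function(path, info) {
  info$package_version <- as.character(utils::packageVersion("sasne"))
  jsonlite::write_json(info, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Write a graph as an edge list
#'
#' Tab-separated `i`, `j`, `weight` with 0-based indices (each undirected
#' edge once, `i < j`), plus a JSON sidecar with `k_used`, `connected`, and
#' `n`.
#'
#' @param graph a `sasne_graph`.
#' @param path output TSV path.
#' @export
write_graph <- function(graph, path) {
  stopifnot(inherits(graph, "sasne_graph"))
  Wt <- methods::as(graph$weights, "TsparseMatrix")
  keep <- Wt@i < Wt@j
  dt <- data.table::data.table(
    i = Wt@i[keep], j = Wt@j[keep], weight = Wt@x[keep]
  )
  data.table::fwrite(dt, path, sep = "\t")
  write_sidecar(path, list(k_used = graph$k_used, connected = graph$connected,
                           n = graph$n))
  invisible(path)
}

#' Write an embedding as CSV
#'
#' Columns `sample_id` (0-based), `y1`, `y2`, with run parameters (seed,
#' perplexity, iterations, distance kind) logged to a JSON sidecar.
#'
#' @param emb a `sasne_embedding`.
#' @param path output CSV path.
#' @export
write_embedding <- function(emb, path) {
  stopifnot(inherits(emb, "sasne_embedding"))
  dt <- data.table::data.table(
    sample_id = seq_len(emb$n) - 1L,
    y1 = emb$coords[, 1], y2 = emb$coords[, 2]
  )
  data.table::fwrite(dt, path)
  write_sidecar(path, list(
    seed = emb$seed, perplexity = emb$params$perplexity,
    iters = emb$params$iters, learning_rate = emb$params$lr,
    distance_kind = emb$distance_kind %||% "unspecified",
    k_used = emb$k_used %||% NA,
    final_kl = tail(emb$kl_trace, 1)
  ))
  invisible(path)
}

#' Read an embedding written by [write_embedding()]
#' @param path CSV path with columns `sample_id`, `y1`, `y2`.
#' @return n x 2 coordinate matrix.
#' @export
read_embedding <- function(path) {
  dt <- data.table::fread(path)
  if (!all(c("y1", "y2") %in% names(dt))) {
    stop("embedding file must have columns y1 and y2", call. = FALSE)
  }
  as.matrix(dt[, c("y1", "y2")])
}
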