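#' Edge indexing for symmetric connectivity matrices
#'
#' An n-node connectivity matrix has `n * (n - 1) / 2` unordered edges.
#' Throughout the package, edges are stored as flat vectors in row-major
#' upper-triangle order with `i < j` and 0-based node indices: positions
#' `(0,1), (0,2), ..., (0,n-1), (1,2), ...` map to flat positions
#' `0 ... n(n-1)/2 - 1`.
#'
#' @param n_nodes number of nodes (>= 2).
#' @return `edge_pairs()`: integer matrix with columns `i`, `j` (0-based,
#'   `i < j`), one row per edge in flat order.
#' @examples
#' edge_pairs(4)
#' @export
edge_pairs <- function(n_nodes) {
  n_nodes <- as.integer(n_nodes)
  if (is.na(n_nodes) || n_nodes < 2L)
    stop("n_nodes must be an integer >= 2")
  i <- rep.int(seq_len(n_nodes - 1L), (n_nodes - 1L):1L)
  j <- sequence((n_nodes - 1L):1L, from = 2:n_nodes)
  cbind(i = i - 1L, j = j - 1L)
}

#' @rdname edge_pairs
#' @return `n_edges()`: the edge count `n(n-1)/2`.
#' @export
n_edges <- function(n_nodes) {
  as.integer(n_nodes * (n_nodes - 1) / 2)
}

#' @rdname edge_pairs
#' @param i,j 0-based node indices, `i != j` (order is irrelevant).
#' @return `edge_flat_index()`: the 0-based flat position of edge (i, j).
#' @export
edge_flat_index <- function(i, j, n_nodes) {
  lo <- pmin(i, j)
  hi <- pmax(i, j)
  if (any(lo == hi)) stop("edge endpoints must be distinct")
  if (any(lo < 0) || any(hi >= n_nodes)) stop("node index out of range")
  # edges before row lo: sum_{k<lo} (n-1-k), then offset within row lo
  as.integer(lo * (n_nodes - 1) - lo * (lo - 1) / 2 + (hi - lo - 1))
}

#' Flatten a connectivity matrix to an edge vector, and back
#'
#' `vectorize_edges()` extracts the upper triangle of a valid FC matrix in
#' the package's canonical edge order; `devectorize_edges()` rebuilds the
#' symmetric matrix (diagonal set to 1, the correlation convention).
#'
#' @param fc symmetric node-by-node matrix with unit diagonal.
#' @param edges numeric vector of length `n_nodes * (n_nodes - 1) / 2`.
#' @param n_nodes node count for `devectorize_edges`.
#' @param check validate the FC invariants first (default TRUE).
#' @return a numeric edge vector, or the reconstructed matrix.
#' @export
vectorize_edges <- function(fc, check = TRUE) {
  if (check) assert_fc(fc)
  n <- nrow(fc)
  ep <- edge_pairs(n)
  fc[ep + 1L]
}

#' @rdname vectorize_edges
#' @export
devectorize_edges <- function(edges, n_nodes) {
  if (length(edges) != n_edges(n_nodes))
    stop(sprintf("edge vector has length %d; expected %d for %d nodes",
                 length(edges), n_edges(n_nodes), n_nodes))
  ep <- edge_pairs(n_nodes) + 1L
  m <- diag(1, n_nodes)
  m[ep] <- edges
  m[ep[, 2:1]] <- edges
  m
}
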