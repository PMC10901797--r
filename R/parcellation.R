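#' Parcellation: node-to-network assignment and edge indexing
#'
#' A parcellation fixes the edge ordering of the feature matrix and assigns
#' each node to one of a small number of canonical networks (10 for the Shen
#' 268-node atlas), which in turn groups edges into subnetworks -- one bin per
#' unordered pair of networks, so `G` networks give `G*(G+1)/2` subnetworks
#' (55 for 10).
#'
#' Edge ordering convention: row-major over the strict upper triangle, i.e.
#' (1,2), (1,3), ..., (1,n), (2,3), ..., (n-1,n). This is fixed package-wide
#' so coefficient vectors are comparable across pipelines.
#'
#' @param node_network integer vector, network index (1-based) per node.
#' @return An object of class `parcellation` with elements `n_nodes`,
#'   `n_networks`, `node_network` and `edge_index` (two-column matrix `a < b`,
#'   one row per edge).
#' @seealso [edge_subnetwork_map()], [vectorize_upper_triangle()]
#' @export
parcellation <- function(node_network) {
  node_network <- as.integer(node_network)
  if (length(node_network) < 2) stop_("need at least 2 nodes")
  if (anyNA(node_network)) stop_("every node must have a network assignment")
  if (any(node_network < 1)) stop_("network indices are 1-based positive integers")
  n <- length(node_network)
  structure(list(n_nodes = n,
                 n_networks = max(node_network),
                 node_network = node_network,
                 edge_index = edge_index_matrix(n)),
            class = "parcellation")
}

#' @export
print.parcellation <- function(x, ...) {
  cat("parcellation:", x$n_nodes, "nodes,", x$n_networks, "networks,",
      nrow(x$edge_index), "edges,",
      x$n_networks * (x$n_networks + 1) / 2, "subnetworks\n")
  invisible(x)
}

#' Read a parcellation from a two-column delimited text file
#'
#' Column 1 is the 1-based node index, column 2 the 1-based network index.
#' Rows may appear in any order but must cover every node exactly once.
#'
#' @param file path; any whitespace- or comma-delimited two-column table.
#' @return A [parcellation()].
#' @export
read_parcellation <- function(file) {
  tab <- utils::read.table(file, header = FALSE,
                           sep = "", colClasses = "numeric")
  if (ncol(tab) == 1)  # comma-separated fallback
    tab <- utils::read.table(file, header = FALSE, sep = ",")
  if (ncol(tab) < 2) stop_("parcellation file must have two columns")
  node <- as.integer(tab[[1]]); net <- as.integer(tab[[2]])
  if (!setequal(node, seq_len(max(node))) || anyDuplicated(node))
    stop_("node indices must cover 1..n_nodes exactly once")
  parcellation(net[order(node)])
}

# row-major strict upper-triangle (a < b) pair list for n nodes
edge_index_matrix <- function(n) {
  a <- rep.int(seq_len(n - 1L), times = (n - 1L):1L)
  b <- unlist(lapply(seq_len(n - 1L), function(i) (i + 1L):n), use.names = FALSE)
  cbind(a = a, b = b)
}

#' Vectorize the upper triangle of a symmetric connectivity matrix
#'
#' Extracts the strict upper triangle in row-major order -- the package's
#' fixed edge ordering -- so that `vectorize_upper_triangle(m)[k]` is the edge
#' `edge_index[k, ]`. The diagonal is ignored.
#'
#' @param m square numeric matrix, symmetric within `tol`.
#' @param tol symmetry tolerance (default `1e-8`).
#' @return Numeric vector of length `n*(n-1)/2`.
#' @export
vectorize_upper_triangle <- function(m, tol = 1e-8) {
  m <- as.matrix(m)
  if (nrow(m) != ncol(m)) stop_("matrix must be square")
  if (max(abs(m - t(m))) > tol) stop_("matrix must be symmetric (within ", tol, ")")
  # t(m)[lower.tri] walks the upper triangle row by row
  t(m)[lower.tri(m)]
}

#' Rebuild a symmetric matrix from an edge vector
#'
#' Inverse of [vectorize_upper_triangle()] (diagonal set to `diag_value`).
#'
#' @param v edge vector of length `n*(n-1)/2`.
#' @param n_nodes node count `n`.
#' @param diag_value value placed on the diagonal (default 0).
#' @return `n x n` symmetric matrix.
#' @export
unvectorize_edges <- function(v, n_nodes, diag_value = 0) {
  p <- n_nodes * (n_nodes - 1) / 2
  if (length(v) != p)
    stop_("edge vector has length ", length(v), " but n_nodes = ", n_nodes,
          " implies ", p)
  m <- matrix(diag_value, n_nodes, n_nodes)
  idx <- edge_index_matrix(n_nodes)
  m[idx] <- v
  m[idx[, 2:1, drop = FALSE]] <- v
  m
}

#' Fisher z-transformation of a correlation
#'
#' `z = atanh(r)`, the variance-stabilizing transform applied to raw node-pair
#' correlations before they are used as edge features.
#'
#' @param r correlation value(s), strictly inside (-1, 1).
#' @return Transformed value(s).
#' @export
fisher_z <- function(r) {
  if (any(!is.finite(r)) || any(abs(r) >= 1))
    stop_("fisher_z is defined for |r| < 1")
  atanh(r)
}

#' Map each edge to its subnetwork
#'
#' A subnetwork is an unordered pair of canonical networks (including
#' within-network pairs); `G` networks give `G*(G+1)/2` subnetworks. Every
#' edge belongs to exactly one subnetwork.
#'
#' @param parc a [parcellation()].
#' @return Integer vector (one entry per edge) of subnetwork indices in
#'   `1..G*(G+1)/2`, with attributes `labels` (subnetwork names `"i-j"`,
#'   `i <= j`) and `n_subnetworks`.
#' @export
edge_subnetwork_map <- function(parc) {
  stopifnot(inherits(parc, "parcellation"))
  g <- parc$node_network
  G <- parc$n_networks
  na <- g[parc$edge_index[, 1]]
  nb <- g[parc$edge_index[, 2]]
  i <- pmin(na, nb); j <- pmax(na, nb)
  # index of pair (i,j), i<=j, in row-major upper-triangle-with-diagonal order
  idx <- (i - 1L) * G - (i - 1L) * i / 2L + j
  pairs <- which(upper.tri(diag(G), diag = TRUE), arr.ind = TRUE)
  pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
  labels <- paste0(pairs[, 1], "-", pairs[, 2])
  structure(as.integer(idx), labels = labels,
            n_subnetworks = as.integer(G * (G + 1L) / 2))
}
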