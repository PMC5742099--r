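# Weighted network metrics
#
# Single distance convention throughout the package: the length of an edge is
# the reciprocal of its weight (strongest connection = shortest path step);
# zero-weight pairs are non-edges.

# igraph object with 1/w distances on edges
as_igraph_dist <- function(W) {
  D <- W
  D[W > 0] <- 1 / W[W > 0]
  igraph::graph_from_adjacency_matrix(D, mode = "undirected", weighted = TRUE)
}

#' All-pairs shortest-path distances under the 1/weight length convention
#'
#' Dijkstra from every source (via igraph). Unreachable pairs are `Inf`.
#'
#' @param W Weighted network matrix.
#' @return Symmetric numeric matrix of path lengths, zero diagonal.
#' @export
shortest_paths_matrix <- function(W) {
  W <- as_weighted_network(W)
  igraph::distances(as_igraph_dist(W), algorithm = "dijkstra")
}

#' Global efficiency (network- and node-level)
#'
#' `GE = mean over ordered pairs of 1/d_ij`, with unreachable pairs
#' contributing 0; the node-level version averages `1/d_ij` over `j != i`.
#' For max-normalised weights GE lies in `[0, 1]`.
#'
#' @param W Weighted network matrix (n >= 2).
#' @return `global_efficiency()`: scalar. `node_global_efficiency()`: named
#'   vector.
#' @export
global_efficiency <- function(W) {
  mean(node_global_efficiency(W))
}

#' @rdname global_efficiency
#' @export
node_global_efficiency <- function(W) {
  W <- as_weighted_network(W)
  if (nrow(W) < 2) {
    abort("Need at least 2 nodes.", class = "connectofuse_invalid_parameter")
  }
  d <- shortest_paths_matrix(W)
  inv <- 1 / d
  inv[!is.finite(inv)] <- 0
  diag(inv) <- 0
  rowSums(inv) / (nrow(W) - 1)
}

#' Local efficiency (network- and node-level)
#'
#' `LE_i` is the global efficiency of the subgraph induced by the neighbours
#' of `i` (with the original weights); nodes with fewer than two neighbours
#' score 0. The network level is the mean over nodes.
#'
#' @param W Weighted network matrix.
#' @return `local_efficiency()`: scalar. `node_local_efficiency()`: named
#'   vector.
#' @export
local_efficiency <- function(W) {
  mean(node_local_efficiency(W))
}

#' @rdname local_efficiency
#' @export
node_local_efficiency <- function(W) {
  W <- as_weighted_network(W)
  n <- nrow(W)
  le <- vapply(seq_len(n), function(i) {
    nb <- which(W[i, ] > 0)
    if (length(nb) < 2) {
      return(0)
    }
    global_efficiency(W[nb, nb, drop = FALSE])
  }, numeric(1))
  names(le) <- rownames(W)
  le
}

#' Path-length summaries: characteristic path length, eccentricity, radius, diameter
#'
#' Computed over finite distances. On a disconnected network the summaries are
#' taken over the largest connected component, with a warning; a network with
#' no edges at all is an error.
#'
#' @param W Weighted network matrix.
#' @return List with `cpl` (mean finite off-diagonal distance over pairs),
#'   `eccentricity` (per-node max distance, NA outside the component used),
#'   `radius`, `diameter`.
#' @export
path_summaries <- function(W) {
  W <- as_weighted_network(W)
  if (n_edges(W) == 0) {
    abort("Network has no edges; path summaries are undefined.",
      class = "connectofuse_invalid_parameter"
    )
  }
  g <- as_igraph_dist(W)
  comp <- igraph::components(g)
  keep <- seq_len(nrow(W))
  if (comp$no > 1) {
    warn("Network is disconnected; path summaries use the largest connected component.")
    keep <- which(comp$membership == which.max(comp$csize))
  }
  d <- shortest_paths_matrix(W[keep, keep, drop = FALSE])
  off <- d[upper.tri(d)]
  ecc_local <- apply(d, 1, max)
  ecc <- rep(NA_real_, nrow(W))
  names(ecc) <- rownames(W)
  ecc[keep] <- ecc_local
  list(
    cpl = mean(off),
    eccentricity = ecc,
    radius = min(ecc_local),
    diameter = max(ecc_local)
  )
}

#' Mean node strength
#'
#' Mean of the row sums of the weight matrix.
#'
#' @param W Weighted network matrix.
#' @return Scalar.
#' @export
mean_strength <- function(W) {
  W <- as_weighted_network(W)
  mean(rowSums(W))
}

#' All network-level metrics as a one-row tibble
#'
#' Global efficiency, local efficiency, characteristic path length, mean
#' eccentricity, radius, diameter and mean strength, as reported per scan and
#' network variant.
#'
#' @param W Weighted network matrix.
#' @param scan_id,subject_id,variant Optional identifier columns.
#' @return One-row tibble.
#' @export
network_metrics <- function(W, scan_id = NA_character_,
                            subject_id = NA_character_,
                            variant = NA_character_) {
  ps <- path_summaries(W)
  tibble::tibble(
    subject_id = subject_id,
    scan_id = scan_id,
    variant = variant,
    global_efficiency = global_efficiency(W),
    local_efficiency = local_efficiency(W),
    char_path_length = ps$cpl,
    eccentricity = mean(ps$eccentricity, na.rm = TRUE),
    radius = ps$radius,
    diameter = ps$diameter,
    mean_strength = mean_strength(W)
  )
}

#' Node-level efficiency table
#'
#' @param W Weighted network matrix.
#' @inheritParams network_metrics
#' @return Tibble with one row per node: `node`, `global_efficiency`,
#'   `local_efficiency`.
#' @export
node_metrics <- function(W, scan_id = NA_character_,
                         subject_id = NA_character_,
                         variant = NA_character_) {
  ge <- node_global_efficiency(W)
  tibble::tibble(
    subject_id = subject_id,
    scan_id = scan_id,
    variant = variant,
    node = names(ge),
    global_efficiency = unname(ge),
    local_efficiency = unname(node_local_efficiency(W))
  )
}
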