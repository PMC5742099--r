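# Node- and cluster-wise lesion (attack) schemes
#
# Each node (or edge class) is attacked in one of three ways — zeroing the
# strongest half of its connections, halving all of them, or both — and the
# diffusion distance between the original and the lesioned network, normalised
# to sum 1 over targets, gives a per-node (per-cluster) importance weight.

lesion_schemes <- c("zero_half", "diminish_half", "combined")

# split an edge index vector into (zeroed, diminished) halves by descending
# weight, deterministic index tie-break; used by zero_half / combined
split_strongest <- function(weights, idx) {
  ord <- idx[order(-weights[idx], idx)]
  n_zero <- ceiling(length(ord) / 2)
  list(zero = ord[seq_len(n_zero)], rest = ord[-seq_len(n_zero)])
}

#' Attack a single node of a weighted network
#'
#' Schemes:
#' * `"zero_half"`: the strongest half (rounded up) of the node's incident
#'   edges, by weight with index tie-break, is set to zero (symmetrically);
#' * `"diminish_half"`: every incident edge is multiplied by 0.5;
#' * `"combined"`: strongest half zeroed, remaining half halved.
#'
#' @param W Weighted network matrix.
#' @param node Node index or label.
#' @param scheme One of `"zero_half"`, `"diminish_half"`, `"combined"`.
#' @return Lesioned weighted network (symmetric).
#' @export
node_attack <- function(W, node, scheme = c("zero_half", "diminish_half", "combined")) {
  scheme <- match.arg(scheme)
  W <- as_weighted_network(W)
  if (is.character(node)) node <- match(node, rownames(W))
  if (is.na(node) || node < 1 || node > nrow(W)) {
    abort("`node` is out of range.", class = "connectofuse_invalid_parameter")
  }
  nb <- which(W[node, ] > 0)
  if (length(nb) == 0) {
    warn("Node is isolated; attack is a no-op.")
    return(W)
  }
  w <- W[node, ]
  if (scheme == "diminish_half") {
    w_new <- w
    w_new[nb] <- w[nb] * 0.5
  } else {
    halves <- split_strongest(w, nb)
    w_new <- w
    w_new[halves$zero] <- 0
    if (scheme == "combined") w_new[halves$rest] <- w[halves$rest] * 0.5
  }
  W[node, ] <- w_new
  W[, node] <- w_new
  W
}

#' Per-node lesion weights from diffusion distances
#'
#' Attacks each node in turn, measures the diffusion distance between the
#' original and the lesioned network, and normalises the n distances to sum 1.
#'
#' @param W Weighted network matrix.
#' @param scheme Attack scheme, see [node_attack()].
#' @param normalization gDDM normalisation mode (default `"none"`: the
#'   original and lesioned networks live on the same scale by construction, so
#'   no per-matrix rescaling should separate them).
#' @return Named nonnegative vector summing to 1.
#' @export
node_lesion_weights <- function(W, scheme = c("zero_half", "diminish_half", "combined"),
                                normalization = c("none", "max", "strength")) {
  scheme <- match.arg(scheme)
  normalization <- match.arg(normalization)
  W <- as_weighted_network(W)
  s0 <- laplacian_spectrum(graph_laplacian(prescale_network(W, normalization)))
  d <- vapply(seq_len(nrow(W)), function(v) {
    Wl <- suppressWarnings(node_attack(W, v, scheme))
    sl <- laplacian_spectrum(graph_laplacian(prescale_network(Wl, normalization)))
    lam <- max(s0$values) + max(sl$values)
    max(maximize_gdd(gdd_profile(s0, sl), lam)$d, 0)
  }, numeric(1))
  names(d) <- rownames(W)
  if (sum(d) == 0) {
    warn("All lesion distances are zero; returning uniform node weights.")
    return(rep(1 / length(d), length(d)) |> stats::setNames(names(d)))
  }
  d / sum(d)
}

#' Partition nodes into clusters for cluster-wise lesions
#'
#' * `"modularity"`: greedy modularity maximisation on the weights
#'   (igraph's fast-greedy agglomeration); returns integer module ids.
#' * `"richclub"`: hubs are nodes whose strength exceeds mean + 1 SD of the
#'   strength distribution; hubs whose within-hub strength exceeds the median
#'   within-hub strength of hubs are labelled `"rc_hub"`, the remaining hubs
#'   `"hub"`, everything else `"non_hub"`.
#'
#' @param W Weighted network matrix (n >= 4; connected for modularity).
#' @param method `"modularity"` or `"richclub"`.
#' @return Named vector of cluster labels (integers or the three hub classes).
#' @export
partition_clusters <- function(W, method = c("modularity", "richclub")) {
  method <- match.arg(method)
  W <- as_weighted_network(W)
  if (nrow(W) < 4) {
    abort("Need at least 4 nodes to partition.", class = "connectofuse_invalid_parameter")
  }
  if (method == "modularity") {
    g <- igraph::graph_from_adjacency_matrix(W, mode = "undirected", weighted = TRUE)
    if (igraph::components(g)$no > 1) {
      abort("Modularity partitioning requires a connected network.",
        class = "connectofuse_invalid_parameter"
      )
    }
    mem <- igraph::membership(igraph::cluster_fast_greedy(g))
    out <- as.integer(mem)
    names(out) <- rownames(W)
    return(out)
  }
  s <- rowSums(W)
  hubs <- which(s > mean(s) + stats::sd(s))
  labels <- rep("non_hub", nrow(W))
  if (length(hubs) > 0) {
    labels[hubs] <- "hub"
    if (length(hubs) >= 2) {
      within_hub <- rowSums(W[hubs, hubs, drop = FALSE])
      rc <- hubs[within_hub > stats::median(within_hub)]
      labels[rc] <- "rc_hub"
    }
  }
  names(labels) <- rownames(W)
  labels
}

# logical mask over the matrix for one targeted edge class
edge_class_mask <- function(labels, target) {
  is_rc <- labels == "rc_hub"
  switch(target,
    within_rc = outer(is_rc, is_rc, `&`),
    within_nonrc = outer(!is_rc, !is_rc, `&`),
    between = outer(is_rc, !is_rc, `&`) | outer(!is_rc, is_rc, `&`),
    abort("Unknown edge class target.", class = "connectofuse_invalid_parameter")
  )
}

# apply a scheme to the edges of W selected by a symmetric logical mask
attack_edge_set <- function(W, mask, scheme) {
  sel <- which(upper.tri(W) & mask & W > 0)
  if (length(sel) == 0) {
    return(W)
  }
  Wl <- W
  if (scheme == "diminish_half") {
    halved <- sel
    zeroed <- integer()
  } else {
    ord <- sel[order(-W[sel], sel)]
    n_zero <- ceiling(length(ord) / 2)
    zeroed <- ord[seq_len(n_zero)]
    halved <- if (scheme == "combined") ord[-seq_len(n_zero)] else integer()
  }
  apply_sym <- function(idx, f) {
    if (length(idx) == 0) {
      return()
    }
    rc <- arrayInd(idx, dim(W))
    Wl[rc] <<- f(Wl[rc])
    Wl[rc[, c(2, 1), drop = FALSE]] <<- Wl[rc]
  }
  apply_sym(zeroed, function(x) 0)
  apply_sym(halved, function(x) x * 0.5)
  Wl
}

#' Cluster-wise attack and lesion weights
#'
#' Applies a node-wise scheme restricted to a targeted edge class and returns
#' the lesioned network; `cluster_lesion_weights()` runs all targets and
#' normalises the diffusion distances to sum 1.
#'
#' For rich-club labels the targets are `"within_rc"`, `"within_nonrc"` and
#' `"between"` (rc-hub vs. rest); for integer module labels each module's
#' within-module edge set is a target.
#'
#' @param W Weighted network matrix.
#' @param labels Cluster labels from [partition_clusters()].
#' @param scheme Attack scheme, see [node_attack()].
#' @param target Edge class (rich-club labels) or module id (module labels).
#' @return `cluster_attack()`: lesioned network. `cluster_lesion_weights()`:
#'   named vector summing to 1 (with a warning and a zero entry for empty edge
#'   classes).
#' @export
cluster_attack <- function(W, labels, scheme = c("zero_half", "diminish_half", "combined"),
                           target = "within_rc") {
  scheme <- match.arg(scheme)
  W <- as_weighted_network(W)
  if (length(labels) != nrow(W)) {
    abort("`labels` must have one entry per node.", class = "connectofuse_invalid_parameter")
  }
  mask <- if (is.character(labels) && any(labels %in% c("rc_hub", "hub", "non_hub"))) {
    edge_class_mask(labels, target)
  } else {
    outer(labels == target, labels == target, `&`)
  }
  if (!any(mask & W > 0 & upper.tri(W))) {
    warn(sprintf("Targeted edge class '%s' is empty; attack is a no-op.", as.character(target)))
  }
  attack_edge_set(W, mask, scheme)
}

#' @rdname cluster_attack
#' @param normalization gDDM normalisation mode, see [node_lesion_weights()].
#' @export
cluster_lesion_weights <- function(W, labels,
                                   scheme = c("zero_half", "diminish_half", "combined"),
                                   normalization = c("none", "max", "strength")) {
  scheme <- match.arg(scheme)
  normalization <- match.arg(normalization)
  W <- as_weighted_network(W)
  targets <- if (is.character(labels) && any(labels %in% c("rc_hub", "hub", "non_hub"))) {
    c("within_rc", "within_nonrc", "between")
  } else {
    sort(unique(labels))
  }
  s0 <- laplacian_spectrum(graph_laplacian(prescale_network(W, normalization)))
  d <- vapply(targets, function(tg) {
    Wl <- suppressWarnings(cluster_attack(W, labels, scheme, target = tg))
    if (identical(Wl, W)) {
      return(0)
    }
    sl <- laplacian_spectrum(graph_laplacian(prescale_network(Wl, normalization)))
    lam <- max(s0$values) + max(sl$values)
    max(maximize_gdd(gdd_profile(s0, sl), lam)$d, 0)
  }, numeric(1))
  names(d) <- as.character(targets)
  if (sum(d) == 0) {
    warn("All cluster lesion distances are zero; returning uniform weights.")
    return(rep(1 / length(d), length(d)) |> stats::setNames(names(d)))
  }
  d / sum(d)
}

#' Node-weighted rescaling of a network stack
#'
#' Multiplies each network node-wise by a lesion-derived importance vector
#' (`W'_ij = w_i w_j W_ij`, kept symmetric), the optional pre-step before the
#' network-wise fusion.
#'
#' @param stack `"nws_stack"` or named list of networks.
#' @param scheme Attack scheme used for the node weights.
#' @return Stack of the same shape with rescaled matrices.
#' @export
node_weighted_stack <- function(stack, scheme = c("zero_half", "diminish_half", "combined")) {
  scheme <- match.arg(scheme)
  out <- lapply(stack, function(W) {
    W <- as_weighted_network(W)
    v <- node_lesion_weights(W, scheme)
    as_weighted_network(W * outer(v, v))
  })
  attributes(out) <- attributes(stack)
  out
}
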