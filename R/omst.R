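# Topological filtering by orthogonal minimal spanning trees (OMST)
#
# Successive edge-disjoint minimum spanning trees/forests are extracted from
# the weight matrix (edge length = 1/weight, so each round keeps the strongest
# backbone of what is left). The cumulative union after r rounds defines a
# candidate filtered network; the round maximising global cost efficiency
# J = GE - Cost is kept, where Cost is the selected fraction of total weight.

# sorted edge list (ascending distance = 1/w, tie-break by (i, j))
sorted_edges <- function(W) {
  ut <- which(upper.tri(W) & W > 0, arr.ind = TRUE)
  if (nrow(ut) == 0) {
    return(tibble::tibble(i = integer(), j = integer(), w = numeric(), d = numeric()))
  }
  e <- tibble::tibble(i = ut[, 1], j = ut[, 2], w = W[ut], d = 1 / W[ut])
  e[order(e$d, e$i, e$j), ]
}

#' Minimum spanning forest of a weighted network
#'
#' Kruskal's algorithm on edge lengths `1/weight` with deterministic
#' tie-breaking by (length, i, j). On a connected graph this is the minimum
#' spanning tree (n - 1 edges); on a disconnected one, a minimum spanning
#' forest with one tree per component.
#'
#' @param W Weighted network matrix.
#' @return Tibble of selected edges (`i`, `j`, `w`).
#' @export
minimum_spanning_forest <- function(W) {
  W <- as_weighted_network(W)
  e <- sorted_edges(W)
  if (nrow(e) == 0) {
    return(tibble::tibble(i = integer(), j = integer(), w = numeric()))
  }
  r <- omst_rounds_cpp(nrow(W), e$i, e$j, 1L)
  e[r == 1L, c("i", "j", "w")]
}

#' Orthogonal minimum spanning trees/forests
#'
#' Round `r` extracts a minimum spanning forest of the graph restricted to
#' edges not selected in earlier rounds; the returned edge sets are pairwise
#' disjoint. Stops when no edges remain or `max_rounds` is reached. Later
#' rounds may be forests rather than trees once edge removal disconnects the
#' residual graph.
#'
#' @param W Weighted network matrix.
#' @param max_rounds Maximum number of rounds (default: run until exhausted).
#' @return List of edge tibbles (`i`, `j`, `w`), one per round.
#' @export
orthogonal_msts <- function(W, max_rounds = Inf) {
  W <- as_weighted_network(W)
  if (max_rounds < 1) {
    abort("`max_rounds` must be >= 1.", class = "connectofuse_invalid_parameter")
  }
  e <- sorted_edges(W)
  if (nrow(e) == 0) {
    return(list())
  }
  mr <- if (is.finite(max_rounds)) as.integer(max_rounds) else nrow(e)
  r <- omst_rounds_cpp(nrow(W), e$i, e$j, mr)
  lapply(seq_len(max(r)), function(k) e[r == k, c("i", "j", "w")])
}

#' Topological filtering at the global-cost-efficiency peak
#'
#' Accumulates OMST rounds and evaluates, for each cumulative union of
#' selected edges, the subgraph carrying the ORIGINAL weights:
#' `J = GE - Cost` with `GE` the weighted global efficiency of the subgraph
#' and `Cost` the selected share of the full network's total weight. The union
#' maximising `J` (ties: fewer rounds) is the filtered network.
#'
#' The curve is evaluated with an exact pruning bound: since the
#' efficiency of any cumulative subgraph cannot exceed the full network's
#' efficiency and `Cost` grows strictly, extraction stops once
#' `GE(full) - Cost(next)` can no longer beat the best `J` seen. Set
#' `prune = FALSE` to force the exhaustive curve.
#'
#' @param W Weighted network matrix with at least one edge.
#' @param max_rounds Optional cap on rounds.
#' @param prune Stop early via the exact upper bound (default TRUE).
#' @return Object of class `"omst_fit"`: `filtered` (weighted network),
#'   `n_rounds` (rounds kept), `curve` (tibble: round, n_edges, cost, ge, j),
#'   `selected` (edge tibble), `input_density`, `filtered_density`.
#' @export
omst_filter <- function(W, max_rounds = Inf, prune = TRUE) {
  W <- as_weighted_network(W)
  if (n_edges(W) == 0) {
    abort("Network has no edges; nothing to filter.",
      class = "connectofuse_invalid_parameter"
    )
  }
  rounds <- orthogonal_msts(W, max_rounds = max_rounds)
  total_weight <- sum(W) / 2
  ge_full <- global_efficiency(W)
  n <- nrow(W)

  Wsel <- matrix(0, n, n, dimnames = dimnames(W))
  curve <- vector("list", length(rounds))
  best_j <- -Inf
  best_round <- 0L
  cum_weight <- 0
  used <- 0L
  for (k in seq_along(rounds)) {
    ed <- rounds[[k]]
    idx <- cbind(ed$i, ed$j)
    Wsel[idx] <- ed$w
    Wsel[idx[, c(2, 1), drop = FALSE]] <- ed$w
    cum_weight <- cum_weight + sum(ed$w)
    cost <- cum_weight / total_weight
    ge <- global_efficiency(Wsel)
    j <- ge - cost
    curve[[k]] <- tibble::tibble(
      round = k, n_edges = nrow(ed) + if (k > 1) curve[[k - 1]]$n_edges else 0L,
      cost = cost, ge = ge, j = j
    )
    used <- k
    if (j > best_j + 1e-15) {
      best_j <- j
      best_round <- k
    }
    # exact bound: any later prefix has GE <= ge_full and cost >= this cost
    if (prune && ge_full - cost <= best_j) break
  }
  curve <- dplyr::bind_rows(curve[seq_len(used)])

  selected <- dplyr::bind_rows(rounds[seq_len(best_round)])
  Wf <- matrix(0, n, n, dimnames = dimnames(W))
  idx <- cbind(selected$i, selected$j)
  Wf[idx] <- selected$w
  Wf[idx[, c(2, 1), drop = FALSE]] <- selected$w

  structure(
    list(
      filtered = as_weighted_network(Wf),
      n_rounds = best_round,
      curve = curve,
      selected = selected,
      input_density = edge_density_w(W),
      filtered_density = edge_density_w(Wf)
    ),
    class = "omst_fit"
  )
}

#' @export
print.omst_fit <- function(x, ...) {
  cat(sprintf(
    "<omst_fit> %d rounds kept, %d edges, density %.1f%% -> %.1f%%, peak J = %.4f\n",
    x$n_rounds, nrow(x$selected), 100 * x$input_density,
    100 * x$filtered_density, max(x$curve$j)
  ))
  invisible(x)
}

#' @export
tidy.omst_fit <- function(x, ...) {
  x$curve
}

#' @export
glance.omst_fit <- function(x, ...) {
  k <- x$n_rounds
  tibble::tibble(
    n_rounds = k,
    n_edges = nrow(x$selected),
    cost = x$curve$cost[k],
    global_efficiency = x$curve$ge[k],
    j = x$curve$j[k],
    input_density = x$input_density,
    filtered_density = x$filtered_density
  )
}

#' Cost-efficiency curve of an OMST fit
#'
#' Plots `J = GE - Cost` against cost per accumulated round, marking the
#' selected peak.
#'
#' @param object `"omst_fit"` object.
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.omst_fit <- function(object, ...) {
  cv <- object$curve
  peak <- cv[object$n_rounds, ]
  ggplot2::ggplot(cv, ggplot2::aes(x = .data$cost, y = .data$j)) +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::geom_point(size = 1.5) +
    ggplot2::geom_point(data = peak, colour = "red", size = 3, shape = 1, stroke = 1.2) +
    ggplot2::labs(
      x = "Cost (selected / total weight)",
      y = "J = GE - Cost",
      title = sprintf("OMST cost-efficiency curve (peak at round %d)", object$n_rounds)
    ) +
    ggplot2::theme_minimal()
}
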