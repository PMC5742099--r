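# Shared fixtures and independent oracles.

# symmetric matrix from an upper-triangle edge list
edge_matrix <- function(n, edges) {
  W <- matrix(0, n, n)
  for (e in edges) {
    W[e[1], e[2]] <- W[e[2], e[1]] <- e[3]
  }
  W
}

complete_graph <- function(n, weights = 1) {
  W <- matrix(weights, n, n)
  W <- (W + t(W)) / 2
  diag(W) <- 0
  W
}

path_graph <- function(n, w = 1) {
  edge_matrix(n, lapply(seq_len(n - 1), function(i) c(i, i + 1, w)))
}

star_graph <- function(n, w = 1) {
  edge_matrix(n, lapply(2:n, function(i) c(1, i, w)))
}

# random dense symmetric weight matrix with positive weights
random_network <- function(n, seed, density = 1, wmin = 0.5, wmax = 1.5) {
  set.seed(seed)
  W <- matrix(0, n, n)
  ut <- upper.tri(W)
  w <- runif(sum(ut), wmin, wmax)
  if (density < 1) w[runif(length(w)) > density] <- 0
  W[ut] <- w
  W + t(W)
}

tiny_geometry <- function(n = 4) {
  tibble::tibble(
    label = paste0("r", seq_len(n)),
    x = as.numeric(seq_len(n)),
    y = 0,
    z = 0,
    voxels = rep(10L, n)
  )
}

# --- independent oracles -----------------------------------------------------

# exhaustive shortest-path oracle: enumerate every simple path (edge length
# 1/w) by depth-first search; independent of igraph
brute_shortest_paths <- function(W) {
  n <- nrow(W)
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  best <- function(from, to) {
    res <- Inf
    visit <- function(v, len, seen) {
      if (v == to) {
        res <<- min(res, len)
        return()
      }
      for (u in which(W[v, ] > 0)) {
        if (!seen[u]) {
          seen[u] <- TRUE
          visit(u, len + 1 / W[v, u], seen)
          seen[u] <- FALSE
        }
      }
    }
    seen <- rep(FALSE, n)
    seen[from] <- TRUE
    visit(from, 0, seen)
    res
  }
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      D[i, j] <- D[j, i] <- best(i, j)
    }
  }
  D
}

brute_global_efficiency <- function(W) {
  D <- brute_shortest_paths(W)
  inv <- 1 / D
  inv[!is.finite(inv)] <- 0
  diag(inv) <- 0
  mean(inv[row(inv) != col(inv)])
}

# ICC(1,1) via stats::aov one-way ANOVA, independent of the sums-of-squares
# implementation
aov_icc11 <- function(M) {
  df <- data.frame(
    value = as.vector(M),
    subject = factor(rep(seq_len(nrow(M)), times = ncol(M)))
  )
  ms <- summary(stats::aov(value ~ subject, data = df))[[1]]$`Mean Sq`
  k <- ncol(M)
  (ms[1] - ms[2]) / (ms[1] + (k - 1) * ms[2])
}

# enumerate all spanning trees of a small graph; returns minimal total
# distance (1/w) and the edge sets achieving it
brute_mst_edges <- function(W) {
  n <- nrow(W)
  ut <- which(upper.tri(W) & W > 0, arr.ind = TRUE)
  m <- nrow(ut)
  best_d <- Inf
  best_sets <- list()
  for (sel in combn(m, n - 1, simplify = FALSE)) {
    sub <- edge_matrix(n, lapply(sel, function(e) c(ut[e, 1], ut[e, 2], W[ut[e, 1], ut[e, 2]])))
    g <- igraph::graph_from_adjacency_matrix(sub > 0, mode = "undirected")
    if (igraph::components(g)$no == 1) {
      d <- sum(1 / W[ut[sel, , drop = FALSE]])
      if (d < best_d - 1e-12) {
        best_d <- d
        best_sets <- list(sel)
      } else if (abs(d - best_d) <= 1e-12) {
        best_sets <- c(best_sets, list(sel))
      }
    }
  }
  list(dist = best_d, sets = best_sets, edges = ut)
}

expect_valid_network <- function(W) {
  expect_true(is.matrix(W))
  expect_equal(W, t(W))
  expect_true(all(diag(W) == 0))
  expect_true(all(is.finite(W)))
  expect_true(all(W >= 0))
}

# small cohort used by several integration tests
small_cohort <- function(seed = 11, n_rois = 15, n_subjects = 2, n_scans = 2,
                         params = cohort_params()) {
  geom <- generate_roi_geometry(n_rois, seed = seed)
  generate_cohort(n_subjects, n_scans, geom, params = params, seed = seed)
}
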