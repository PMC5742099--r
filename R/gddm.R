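# Graph diffusion distance (gDDM)
#
# Distance between two weighted graphs of equal size: the maximum over
# diffusion time t of ||exp(-t L1) - exp(-t L2)||_F^2, where L = D - W is the
# combinatorial graph Laplacian and exp(-tL) its heat (Laplacian exponential)
# kernel. Both t -> 0 and t -> inf drive the difference to zero (identity and
# component-wise projector limits), so an interior maximum exists whenever the
# two graphs differ.

#' Combinatorial graph Laplacian
#'
#' `L = D - W` with `D = diag(rowSums(W))`. Rows sum to zero and `L` is
#' positive semidefinite for any valid weighted network.
#'
#' @param W Weighted network matrix.
#' @return Laplacian matrix.
#' @export
graph_laplacian <- function(W) {
  W <- as_weighted_network(W)
  diag(rowSums(W)) - W
}

#' Laplacian exponential diffusion kernel
#'
#' `exp(-tL)` computed through the spectral decomposition `L = V diag(l) V'`
#' as `V diag(exp(-t l)) V'`. The kernel is symmetric, doubly stochastic
#' (every row sums to 1) and has entries in `[0, 1]`.
#'
#' @param L Graph Laplacian (from [graph_laplacian()]).
#' @param t Diffusion time (> 0).
#' @return List with elements `t` and `K` (the kernel matrix).
#' @export
diffusion_kernel <- function(L, t) {
  if (!is.numeric(t) || length(t) != 1 || t <= 0) {
    abort("`t` must be a single positive number.", class = "connectofuse_invalid_parameter")
  }
  es <- laplacian_spectrum(L)
  K <- tcrossprod(sweep(es$vectors, 2, exp(-t * es$values), `*`), es$vectors)
  K <- (K + t(K)) / 2
  list(t = t, K = K)
}

# spectral decomposition of a Laplacian with ascending, zero-clipped
# eigenvalues and orthonormal eigenvectors
laplacian_spectrum <- function(L) {
  es <- eigen(L, symmetric = TRUE)
  vals <- rev(es$values)
  vals[vals < 0 & vals > -1e-10] <- 0
  list(values = vals, vectors = es$vectors[, rev(seq_along(vals)), drop = FALSE])
}

# rescale a network before comparison; the nine weightings carry
# incommensurate units, so "max" (per-matrix max-normalisation) is the default
prescale_network <- function(W, mode = c("max", "none", "strength")) {
  mode <- match.arg(mode)
  if (mode == "none") {
    return(W)
  }
  denom <- switch(mode,
    max = max(W),
    strength = sum(W)
  )
  if (denom <= 0) W else W / denom
}

# distance profile machinery: with M = V1'V2 and Q = M^2 (elementwise),
# ||exp(-tL1)-exp(-tL2)||_F^2 = sum(exp(-2t l1)) + sum(exp(-2t l2))
#                               - 2 * exp(-t l1)' Q exp(-t l2)
gdd_profile <- function(spec1, spec2) {
  Q <- crossprod(spec1$vectors, spec2$vectors)^2
  l1 <- spec1$values
  l2 <- spec2$values
  function(t) {
    a <- exp(-t * l1)
    b <- exp(-t * l2)
    sum(a^2) + sum(b^2) - 2 * drop(a %*% Q %*% b)
  }
}

# maximise a distance profile over t: log-spaced grid scaled by the joint
# spectral radius, then bounded refinement around the grid argmax
maximize_gdd <- function(profile, lambda_max, n_grid = 100,
                         t_min = 1e-3, t_max = 1e3) {
  scale <- if (lambda_max > 0) lambda_max else 1
  grid <- exp(seq(log(t_min), log(t_max), length.out = n_grid)) / scale
  vals <- vapply(grid, profile, numeric(1))
  k <- which.max(vals)
  lo <- grid[max(1, k - 1)]
  hi <- grid[min(length(grid), k + 1)]
  opt <- optimize(profile, lower = lo, upper = hi, maximum = TRUE, tol = 1e-12)
  if (opt$objective >= vals[k]) {
    list(d = opt$objective, t_star = opt$maximum)
  } else {
    list(d = vals[k], t_star = grid[k])
  }
}

#' Graph diffusion distance between two weighted networks
#'
#' Maximises `||exp(-t L1) - exp(-t L2)||_F^2` over diffusion time `t`. The
#' search evaluates the profile on a 100-point logarithmic grid spanning
#' `[1e-3, 1e3] / lambda_max(L1 + L2)` and refines around the grid argmax with
#' bounded scalar optimisation.
#'
#' @param W1,W2 Weighted network matrices of equal size.
#' @param normalization One of `"max"` (default; each matrix divided by its
#'   largest entry before comparison), `"strength"` (divided by its total
#'   weight) or `"none"`. The nine tractography weightings carry
#'   incommensurate units, so some rescaling is almost always wanted.
#' @param n_grid,t_min,t_max Search-grid options (see Details).
#' @return List with `d` (the distance, >= 0) and `t_star` (the maximising
#'   diffusion time).
#' @export
gddm_distance <- function(W1, W2, normalization = c("max", "none", "strength"),
                          n_grid = 100, t_min = 1e-3, t_max = 1e3) {
  normalization <- match.arg(normalization)
  W1 <- as_weighted_network(W1)
  W2 <- as_weighted_network(W2)
  if (nrow(W1) != nrow(W2)) {
    abort("Networks must have the same number of nodes.",
      class = "connectofuse_invalid_parameter"
    )
  }
  s1 <- laplacian_spectrum(graph_laplacian(prescale_network(W1, normalization)))
  s2 <- laplacian_spectrum(graph_laplacian(prescale_network(W2, normalization)))
  lam <- max(s1$values) + max(s2$values)
  res <- maximize_gdd(gdd_profile(s1, s2), lam,
    n_grid = n_grid, t_min = t_min, t_max = t_max
  )
  list(d = max(res$d, 0), t_star = res$t_star)
}

#' Pairwise diffusion-distance matrix over a collection of networks
#'
#' Eigendecomposes each (prescaled) Laplacian once and reuses the spectra
#' across pairs, so the cost is one decomposition per network plus one small
#' profile search per pair.
#'
#' @param networks Named list of weighted network matrices (equal size).
#' @param normalization,n_grid,t_min,t_max As in [gddm_distance()].
#' @return Object of class `"dissimilarity"`: list with `D` (symmetric
#'   labelled distance matrix, zero diagonal), `t_star` (matrix of maximising
#'   times) and `options`.
#' @export
pairwise_dissimilarity <- function(networks,
                                   normalization = c("max", "none", "strength"),
                                   n_grid = 100, t_min = 1e-3, t_max = 1e3) {
  normalization <- match.arg(normalization)
  m <- length(networks)
  if (m < 2) {
    abort("Need at least 2 networks.", class = "connectofuse_invalid_parameter")
  }
  labels <- names(networks) %||% paste0("net_", seq_len(m))
  specs <- lapply(networks, function(W) {
    laplacian_spectrum(graph_laplacian(prescale_network(as_weighted_network(W), normalization)))
  })
  D <- matrix(0, m, m, dimnames = list(labels, labels))
  Tm <- matrix(NA_real_, m, m, dimnames = list(labels, labels))
  for (a in seq_len(m - 1)) {
    for (b in (a + 1):m) {
      lam <- max(specs[[a]]$values) + max(specs[[b]]$values)
      res <- maximize_gdd(gdd_profile(specs[[a]], specs[[b]]), lam,
        n_grid = n_grid, t_min = t_min, t_max = t_max
      )
      D[a, b] <- D[b, a] <- max(res$d, 0)
      Tm[a, b] <- Tm[b, a] <- res$t_star
    }
  }
  structure(
    list(
      D = D, t_star = Tm,
      options = list(
        normalization = normalization, n_grid = n_grid,
        t_min = t_min, t_max = t_max
      )
    ),
    class = "dissimilarity"
  )
}

#' @export
print.dissimilarity <- function(x, ...) {
  cat(sprintf(
    "<dissimilarity> %d networks, normalization = %s\n",
    nrow(x$D), x$options$normalization
  ))
  print(round(x$D, 4))
  invisible(x)
}

#' Write a dissimilarity matrix (CSV) with a JSON options sidecar
#' @param d `"dissimilarity"` object.
#' @param path CSV path; options go to `paste0(path, ".json")`.
#' @return `path`, invisibly.
#' @export
write_dissimilarity <- function(d, path) {
  write_matrix(d$D, path)
  jsonlite::write_json(d$options, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}
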