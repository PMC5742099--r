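#' Validate (and label) a weighted network matrix
#'
#' A weighted network here is a plain numeric matrix that is square, symmetric,
#' nonnegative, finite, and has a zero diagonal. Undirected edges are the
#' nonzero off-diagonal entries. All graph operations in the package accept
#' such matrices and call this validator at their boundary.
#'
#' @param W Square numeric matrix.
#' @param labels Optional character vector of node labels; defaults to existing
#'   dimnames or `"roi_1" ... "roi_n"`.
#' @param tol Symmetry tolerance. Asymmetries below `tol` (relative to the
#'   largest entry) are symmetrised by averaging; larger ones are an error.
#' @return The validated matrix with dimnames set, invisibly classed as a
#'   plain matrix (no S4 wrapper).
#' @export
as_weighted_network <- function(W, labels = NULL, tol = 1e-9) {
  if (!is.matrix(W) || !is.numeric(W)) {
    abort("`W` must be a numeric matrix.", class = "connectofuse_invalid_network")
  }
  if (nrow(W) != ncol(W)) {
    abort("`W` must be square.", class = "connectofuse_invalid_network")
  }
  if (any(!is.finite(W))) {
    abort("`W` must be finite.", class = "connectofuse_invalid_network")
  }
  scale <- max(abs(W), 1)
  asym <- max(abs(W - t(W)))
  if (asym > tol * scale) {
    idx <- which(abs(W - t(W)) == asym, arr.ind = TRUE)[1, ]
    abort(
      sprintf(
        "`W` is asymmetric beyond tolerance at cell [%d, %d] (|w_ij - w_ji| = %.3g).",
        idx[1], idx[2], asym
      ),
      class = "connectofuse_invalid_network"
    )
  }
  if (asym > 0) {
    warn("Small asymmetry in `W`; symmetrising by averaging.")
    W <- (W + t(W)) / 2
  }
  if (any(W < 0)) {
    idx <- which(W < 0, arr.ind = TRUE)[1, ]
    abort(
      sprintf("`W` has a negative entry at cell [%d, %d].", idx[1], idx[2]),
      class = "connectofuse_invalid_network"
    )
  }
  diag(W) <- 0
  labels <- labels %||% rownames(W) %||% paste0("roi_", seq_len(nrow(W)))
  dimnames(W) <- list(labels, labels)
  W
}

#' Strict validity check without modification
#' @param W matrix to check.
#' @return TRUE invisibly; errors otherwise.
#' @keywords internal
check_network <- function(W) {
  as_weighted_network(W)
  invisible(TRUE)
}

# number of undirected edges (nonzero upper-triangle entries)
n_edges <- function(W) sum(W[upper.tri(W)] > 0)

# edge density relative to the complete graph
edge_density_w <- function(W) {
  n <- nrow(W)
  n_edges(W) / (n * (n - 1) / 2)
}
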