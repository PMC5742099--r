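# Linear integration of the NWS networks into a single fused graph (IWSBN)

#' Integration weights from a dissimilarity matrix
#'
#' Row sums of the pairwise diffusion-distance matrix, normalised to total 1.
#' A weighting that is more dissimilar from the others therefore receives a
#' larger weight; an `inverse` mode (1/rowsum, renormalised) is available.
#'
#' @param D Square symmetric nonnegative dissimilarity matrix (or a
#'   `"dissimilarity"` object).
#' @param mode `"rowsum"` (default) or `"inverse"`.
#' @return Named numeric vector of weights summing to 1.
#' @export
integration_weights <- function(D, mode = c("rowsum", "inverse")) {
  mode <- match.arg(mode)
  if (inherits(D, "dissimilarity")) D <- D$D
  D <- as_weighted_network(D)
  rs <- rowSums(D)
  if (sum(rs) <= 1e-10 * nrow(D)) { # numerically zero: identical networks
    abort(
      "All pairwise dissimilarities are zero: the networks are identical and integration weights are undefined.",
      class = "connectofuse_degenerate_dissimilarity"
    )
  }
  w <- if (mode == "rowsum") rs else {
    inv <- ifelse(rs > 0, 1 / rs, 0)
    inv
  }
  w / sum(w)
}

#' Fuse a stack of networks into an integrated weighted network
#'
#' Computes `IWSBN = sum_k l_w[k] * prescale(W_k)` over the stack. With the
#' default prescaling every weighting is first max-normalised to `[0, 1]`, so
#' the fusion is a convex combination of commensurate matrices and the result
#' is almost fully weighted (its support is the union of the inputs').
#'
#' @param stack `"nws_stack"` or named list of weighted networks.
#' @param weights Named weights from [integration_weights()]; if `NULL`, they
#'   are computed from [pairwise_dissimilarity()] of the prescaled stack, with
#'   a uniform fallback (and a warning) when all dissimilarities are zero.
#' @param prescale `"max"` (default), `"strength"` or `"none"`.
#' @param normalization gDDM normalisation used when `weights` is `NULL`.
#' @return List of class `"iwsbn"`: `W` (the fused network), `weights`,
#'   `prescale`, plus the scan/subject ids when present on the stack.
#' @export
integrate_nws <- function(stack, weights = NULL,
                          prescale = c("max", "none", "strength"),
                          normalization = c("max", "none", "strength")) {
  prescale <- match.arg(prescale)
  normalization <- match.arg(normalization)
  nets <- lapply(stack, as_weighted_network)
  if (length(nets) < 2) {
    abort("Need at least 2 networks to integrate.", class = "connectofuse_invalid_parameter")
  }
  ns <- vapply(nets, nrow, integer(1))
  if (length(unique(ns)) != 1) {
    abort("All networks must have the same size.", class = "connectofuse_invalid_parameter")
  }
  scaled <- lapply(nets, prescale_network, mode = prescale)
  if (is.null(weights)) {
    weights <- tryCatch(
      integration_weights(pairwise_dissimilarity(scaled, normalization = normalization)),
      connectofuse_degenerate_dissimilarity = function(e) {
        warn("All pairwise dissimilarities are zero; falling back to uniform weights.")
        w <- rep(1 / length(nets), length(nets))
        names(w) <- names(nets)
        w
      }
    )
  }
  if (!setequal(names(weights), names(nets))) {
    abort("`weights` names must match the stack's network names.",
      class = "connectofuse_invalid_parameter"
    )
  }
  if (any(weights < 0) || abs(sum(weights) - 1) > 1e-8) {
    abort("`weights` must be nonnegative and sum to 1.",
      class = "connectofuse_invalid_parameter"
    )
  }
  W <- Reduce(`+`, purrr::map2(scaled[names(weights)], weights, `*`))
  structure(
    list(
      W = as_weighted_network(W),
      weights = weights,
      prescale = prescale,
      scan_id = attr(stack, "scan_id"),
      subject_id = attr(stack, "subject_id")
    ),
    class = "iwsbn"
  )
}

#' @export
print.iwsbn <- function(x, ...) {
  cat(sprintf(
    "<iwsbn> %d ROIs, density %.1f%%, prescale = %s\n",
    nrow(x$W), 100 * edge_density_w(x$W), x$prescale
  ))
  cat("weights:\n")
  print(round(x$weights, 4))
  invisible(x)
}

#' Integrate the stack as three triads of weightings
#'
#' Applies the same dissimilarity-weighted fusion separately to the tensor
#' triad (FA, MD, RD), the geometry triad (ATL, ED, SD) and the streamline
#' triad (TV, NSTR, PSTR).
#'
#' @param stack `"nws_stack"` with all nine weightings.
#' @param triads Named list of character triples; the default is the canonical
#'   split in stack order.
#' @inheritParams integrate_nws
#' @return Named list of three `"iwsbn"` objects.
#' @export
triad_integration <- function(stack,
                              triads = list(
                                tensor = c("FA", "MD", "RD"),
                                geometry = c("ATL", "ED", "SD"),
                                streamline = c("TV", "NSTR", "PSTR")
                              ),
                              prescale = c("max", "none", "strength"),
                              normalization = c("max", "none", "strength")) {
  prescale <- match.arg(prescale)
  normalization <- match.arg(normalization)
  lapply(triads, function(keys) {
    missing <- setdiff(keys, names(stack))
    if (length(missing) > 0) {
      abort(paste0("Incomplete triad; missing: ", paste(missing, collapse = ", ")),
        class = "connectofuse_invalid_parameter"
      )
    }
    sub <- stack[keys]
    attributes(sub) <- c(attributes(sub), list(
      scan_id = attr(stack, "scan_id"),
      subject_id = attr(stack, "subject_id")
    ))
    integrate_nws(sub, prescale = prescale, normalization = normalization)
  })
}
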