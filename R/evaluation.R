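# Test-retest reliability and subject discriminability

#' Intraclass correlation coefficient for a subjects x scans table
#'
#' Single-rater ICC forms (Shrout-Fleiss family) from the one- and two-way
#' mean squares:
#' * `"1_1"` (default) one-way random: `(MSB - MSW) / (MSB + (k-1) MSW)` with
#'   subjects as the random factor and scans as indistinguishable repeats;
#' * `"2_1"` two-way random, absolute agreement;
#' * `"3_1"` two-way mixed, consistency.
#'
#' @param table Numeric matrix (subjects x scans) or a long tibble with
#'   columns `subject_id`, `scan` (or `scan_id`) and `value`.
#' @param form One of `"1_1"`, `"2_1"`, `"3_1"`.
#' @return Object of class `"icc_fit"`: `icc`, `form`, mean squares, design
#'   size.
#' @export
icc <- function(table, form = c("1_1", "2_1", "3_1")) {
  form <- match.arg(form)
  M <- as_metric_matrix(table)
  n <- nrow(M)
  k <- ncol(M)
  if (n < 2 || k < 2) {
    abort("Need at least 2 subjects and 2 scans.", class = "connectofuse_invalid_parameter")
  }
  if (anyNA(M)) {
    abort("Metric table must be complete (no missing cells).",
      class = "connectofuse_invalid_parameter"
    )
  }
  grand <- mean(M)
  if (max(M) - min(M) == 0) {
    abort("All values identical: between- and within-subject variance are both zero, ICC is undefined.",
      class = "connectofuse_degenerate_icc"
    )
  }
  row_m <- rowMeans(M)
  col_m <- colMeans(M)
  ssb <- k * sum((row_m - grand)^2) # between subjects
  ssc <- n * sum((col_m - grand)^2) # between scans (columns)
  sst <- sum((M - grand)^2)
  ssw <- sst - ssb # within subjects (one-way residual)
  sse <- sst - ssb - ssc # two-way residual
  msb <- ssb / (n - 1)
  msw <- ssw / (n * (k - 1))
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  value <- switch(form,
    "1_1" = (msb - msw) / (msb + (k - 1) * msw),
    "2_1" = (msb - mse) / (msb + (k - 1) * mse + k * (msc - mse) / n),
    "3_1" = (msb - mse) / (msb + (k - 1) * mse)
  )
  structure(
    list(
      icc = value, form = form, n_subjects = n, n_scans = k,
      ms = c(msb = msb, msw = msw, msc = msc, mse = mse)
    ),
    class = "icc_fit"
  )
}

as_metric_matrix <- function(table) {
  if (is.matrix(table)) {
    return(table)
  }
  scan_col <- intersect(c("scan", "scan_id"), names(table))[1]
  if (is.na(scan_col) || !all(c("subject_id", "value") %in% names(table))) {
    abort("Long metric tables need `subject_id`, `scan`/`scan_id` and `value` columns.",
      class = "connectofuse_invalid_parameter"
    )
  }
  wide <- tidyr::pivot_wider(
    table[, c("subject_id", scan_col, "value")],
    names_from = dplyr::all_of(scan_col), values_from = "value"
  )
  M <- as.matrix(wide[, -1])
  rownames(M) <- wide$subject_id
  M
}

#' @export
print.icc_fit <- function(x, ...) {
  cat(sprintf(
    "<icc_fit> ICC(%s) = %.4f  (%d subjects x %d scans)\n",
    sub("_", ",", x$form), x$icc, x$n_subjects, x$n_scans
  ))
  invisible(x)
}

#' @export
tidy.icc_fit <- function(x, ...) {
  tibble::tibble(
    term = c("ms_between_subjects", "ms_within_subjects", "ms_between_scans", "ms_residual"),
    estimate = unname(x$ms)
  )
}

#' @export
glance.icc_fit <- function(x, ...) {
  tibble::tibble(
    icc = x$icc, form = x$form,
    n_subjects = x$n_subjects, n_scans = x$n_scans
  )
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Exact enumeration of all rank assignments (with midranks for ties) when the
#' combined sample size is at most 12; tie-corrected normal approximation with
#' continuity correction otherwise. The statistic is the rank sum of `x`.
#'
#' @param x,y Numeric samples (both nonempty).
#' @return List with `statistic` (rank sum of `x`), `p_value`, `method`.
#' @export
wilcoxon_ranksum <- function(x, y) {
  if (length(x) == 0 || length(y) == 0) {
    abort("Both samples must be nonempty.", class = "connectofuse_invalid_parameter")
  }
  n1 <- length(x)
  n2 <- length(y)
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_len(n1)])
  e_w <- n1 * (n1 + n2 + 1) / 2
  if (n1 + n2 <= 12) {
    sets <- combn(n1 + n2, n1)
    w_all <- colSums(matrix(r[sets], nrow = n1))
    p <- mean(abs(w_all - e_w) >= abs(w_obs - e_w) - 1e-12)
    method <- "exact enumeration"
  } else {
    ties <- table(r)
    tie_term <- sum(ties^3 - ties) / ((n1 + n2) * (n1 + n2 - 1))
    sd_w <- sqrt(n1 * n2 / 12 * (n1 + n2 + 1 - tie_term))
    z <- (abs(w_obs - e_w) - 0.5) / sd_w
    p <- min(1, 2 * pnorm(-max(z, 0)))
    method <- "normal approximation"
  }
  list(statistic = w_obs, p_value = p, method = method)
}

#' Leave-one-out k-NN scan recognition from a distance matrix
#'
#' Each scan is assigned the majority subject label among its `k` nearest
#' other scans. Ties are broken by the smaller summed distance to the tied
#' label's neighbours, then by the smaller subject index. Accuracy is the
#' fraction of scans assigned to their own subject.
#'
#' @param D Symmetric distance matrix across all scans (or a
#'   `"dissimilarity"` object).
#' @param labels Subject label per row of `D`.
#' @param k Number of neighbours (default 4; must satisfy `k < nrow(D) - 1`).
#' @return List of class `"knn_recognition"`: `accuracy`, `k`, `assignments`
#'   tibble (scan, true, predicted, correct).
#' @export
knn_recognition <- function(D, labels, k = 4) {
  if (inherits(D, "dissimilarity")) D <- D$D
  if (k <= 0) {
    abort("`k` must be positive.", class = "connectofuse_invalid_parameter")
  }
  m <- nrow(D)
  if (k >= m - 1) {
    abort("`k` must be smaller than the number of other scans.",
      class = "connectofuse_invalid_parameter"
    )
  }
  if (length(labels) != m) {
    abort("`labels` must have one entry per row of `D`.",
      class = "connectofuse_invalid_parameter"
    )
  }
  labels <- as.character(labels)
  subj_levels <- sort(unique(labels))
  pred <- character(m)
  for (s in seq_len(m)) {
    d <- D[s, -s]
    lab <- labels[-s]
    ord <- order(d, seq_along(d))
    nn <- ord[seq_len(k)]
    votes <- table(lab[nn])
    top <- names(votes)[votes == max(votes)]
    if (length(top) > 1) {
      sums <- vapply(top, function(lv) sum(d[nn][lab[nn] == lv]), numeric(1))
      top <- top[sums == min(sums)]
      if (length(top) > 1) {
        top <- top[order(match(top, subj_levels))][1]
      }
    }
    pred[s] <- top[1]
  }
  assignments <- tibble::tibble(
    scan = rownames(D) %||% paste0("scan_", seq_len(m)),
    true = labels,
    predicted = pred,
    correct = labels == pred
  )
  structure(
    list(accuracy = mean(assignments$correct), k = k, assignments = assignments),
    class = "knn_recognition"
  )
}

#' @export
print.knn_recognition <- function(x, ...) {
  cat(sprintf(
    "<knn_recognition> k = %d, accuracy = %.3f (%d / %d scans)\n",
    x$k, x$accuracy, sum(x$assignments$correct), nrow(x$assignments)
  ))
  invisible(x)
}

#' Quality-of-clustering index of a scans x scans distance matrix
#'
#' Ratio of the (equalised) mean between-subject to mean within-subject
#' diffusion distance over a complete subjects x scans design:
#' \deqn{QCI = \frac{scans(scans-1)/2}{scans^2} \times
#'   \frac{\sum_{su1<su2}\sum_{l,m} D(su1,l; su2,m) / [subjects(subjects-1)/2]}
#'        {\sum_{su}\sum_{l<m} D(su,l; su,m) / subjects}}
#' A constant distance matrix scores exactly 1; larger values mean scans of
#' the same subject sit closer together than scans of different subjects. The
#' index is invariant to rescaling of `D`.
#'
#' @param D Distance matrix across all scans (or `"dissimilarity"` object).
#' @param subjects Subject label per row.
#' @return Scalar QCI.
#' @export
qci <- function(D, subjects) {
  if (inherits(D, "dissimilarity")) D <- D$D
  subjects <- as.character(subjects)
  if (length(subjects) != nrow(D)) {
    abort("`subjects` must label every row of `D`.", class = "connectofuse_invalid_parameter")
  }
  tab <- table(subjects)
  if (length(tab) < 2 || any(tab < 2) || length(unique(tab)) != 1) {
    abort("Need a complete design: >= 2 subjects, each with the same number (>= 2) of scans.",
      class = "connectofuse_invalid_parameter"
    )
  }
  n_sub <- length(tab)
  n_scan <- unname(tab[1])
  idx <- split(seq_along(subjects), subjects)

  between <- 0
  for (a in seq_len(n_sub - 1)) {
    for (b in (a + 1):n_sub) {
      between <- between + sum(D[idx[[a]], idx[[b]]])
    }
  }
  within <- sum(vapply(idx, function(ii) {
    Dm <- D[ii, ii, drop = FALSE]
    sum(Dm[upper.tri(Dm)])
  }, numeric(1)))
  if (within == 0) {
    abort("Within-subject distances are all zero; QCI is undefined.",
      class = "connectofuse_degenerate_qci"
    )
  }
  prefactor <- (n_scan * (n_scan - 1) / 2) / n_scan^2
  numerator <- between / (n_sub * (n_sub - 1) / 2)
  denominator <- within / n_sub
  prefactor * numerator / denominator
}

#' Classical multidimensional-scaling embedding of a distance matrix
#'
#' Double-centering (Torgerson) MDS via [stats::cmdscale()].
#'
#' @param D Distance matrix (or `"dissimilarity"` object).
#' @param dims Embedding dimension (default 3; must be < n).
#' @param labels Optional row labels.
#' @return Tibble with `label` and coordinate columns `dim1..dimk`.
#' @export
mds_embed <- function(D, dims = 3, labels = NULL) {
  if (inherits(D, "dissimilarity")) D <- D$D
  n <- nrow(D)
  if (dims >= n) {
    abort("`dims` must be smaller than the number of points.",
      class = "connectofuse_invalid_parameter"
    )
  }
  # cmdscale warns when the spectrum supports fewer than `dims` axes; the
  # missing coordinates are legitimately zero and padded below
  X <- suppressWarnings(stats::cmdscale(D, k = dims))
  if (ncol(X) < dims) { # degenerate spectra: pad with zero coordinates
    X <- cbind(X, matrix(0, n, dims - ncol(X)))
  }
  colnames(X) <- paste0("dim", seq_len(dims))
  dplyr::bind_cols(
    tibble::tibble(label = labels %||% rownames(D) %||% paste0("p", seq_len(n))),
    tibble::as_tibble(X)
  )
}

#' Plot a 2D projection of an MDS embedding coloured by subject
#'
#' @param embedding Tibble from [mds_embed()].
#' @param subjects Subject label per point.
#' @return A ggplot.
#' @export
plot_embedding <- function(embedding, subjects) {
  df <- dplyr::mutate(embedding, subject = as.character(subjects))
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$dim1, y = .data$dim2,
    colour = .data$subject, group = .data$subject
  )) +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "MDS dim 1", y = "MDS dim 2", colour = "subject") +
    ggplot2::theme_minimal()
}

#' ICC over a long table of network metrics
#'
#' Convenience wrapper: computes one ICC per (variant, metric) combination in
#' a metrics table such as produced by [cohort_pipeline()].
#'
#' @param metrics Long tibble with `subject_id`, `scan_id`, `variant` and one
#'   column per metric.
#' @param form ICC form, see [icc()].
#' @return Tibble: `variant`, `metric`, `icc`, `form`.
#' @export
icc_report <- function(metrics, form = "1_1") {
  metric_cols <- setdiff(
    names(metrics)[vapply(metrics, is.numeric, logical(1))],
    c("subject_id", "scan_id", "variant")
  )
  long <- tidyr::pivot_longer(metrics,
    cols = dplyr::all_of(metric_cols),
    names_to = "metric", values_to = "value"
  )
  # scan ids may embed the subject (sub_01.scan_01); ICC needs the scan
  # occasion within each subject
  long <- long |>
    dplyr::group_by(.data$variant, .data$metric, .data$subject_id) |>
    dplyr::mutate(occasion = dplyr::row_number(.data$scan_id)) |>
    dplyr::ungroup()
  long |>
    dplyr::group_by(.data$variant, .data$metric) |>
    dplyr::group_modify(function(df, key) {
      tbl <- tibble::tibble(
        subject_id = df$subject_id, scan = df$occasion, value = df$value
      )
      fit <- tryCatch(
        icc(tbl, form = form),
        connectofuse_degenerate_icc = function(e) NULL
      )
      tibble::tibble(icc = if (is.null(fit)) NA_real_ else fit$icc, form = form)
    }) |>
    dplyr::ungroup()
}
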