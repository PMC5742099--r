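# Network weighting strategies (NWS)
#
# Nine edge weightings per scan: FA, MD, RD (tensor metrics averaged along the
# tract, count-weighted across records), ATL (average tract length), ED
# (Euclidean centroid distance, dense by construction), SD (streamline density
# corrected for ROI size), TV (tract volume), NSTR (streamline count), PSTR
# (proportion of streamlines over the whole brain).

#' Names of the nine network weighting strategies, in canonical order
#' @export
nws_names <- function() c("FA", "MD", "RD", "ATL", "ED", "SD", "TV", "NSTR", "PSTR")

#' Filter a tract table by minimum contiguous white-matter length
#'
#' Discards records whose streamlines pass through less than `l_mm` of white
#' matter; `l_mm = 0` keeps everything.
#'
#' @param tracts Tract-table tibble with a `wm_length_mm` column.
#' @param l_mm Threshold in mm (>= 0).
#' @return Filtered tibble.
#' @export
length_filter <- function(tracts, l_mm) {
  if (!is.numeric(l_mm) || length(l_mm) != 1 || l_mm < 0) {
    abort("`l_mm` must be a single nonnegative number.",
      class = "connectofuse_invalid_parameter"
    )
  }
  if (l_mm == 0) {
    return(tracts)
  }
  dplyr::filter(tracts, .data$wm_length_mm >= l_mm)
}

#' Inclusive arithmetic threshold grid
#'
#' The default sweep of the white-matter length filter runs from 0 to 6.0 mm
#' in 0.5 mm increments (13 thresholds).
#'
#' @param start_mm,stop_mm,step_mm Grid bounds and step (mm).
#' @return Numeric vector of thresholds; never overshoots `stop_mm`.
#' @export
threshold_grid <- function(start_mm = 0, stop_mm = 6.0, step_mm = 0.5) {
  if (step_mm <= 0) {
    abort("`step_mm` must be positive.", class = "connectofuse_invalid_parameter")
  }
  if (stop_mm < start_mm) {
    abort("`stop_mm` must be >= `start_mm`.", class = "connectofuse_invalid_parameter")
  }
  n_steps <- floor((stop_mm - start_mm) / step_mm + 1e-9)
  start_mm + step_mm * (0:n_steps)
}

#' Streamline density corrected for ROI size
#'
#' `w = 2 / (g_i + g_j) * |S_ij|`, where `g_i`, `g_j` are the gray-matter
#' voxel counts of the two regions and `|S_ij|` the number of interconnecting
#' streamlines.
#'
#' @param g_i,g_j Gray-matter voxel counts (>= 1); vectorised.
#' @param n_streamlines Streamline count (>= 0); vectorised.
#' @return Numeric weight(s).
#' @export
sd_weight <- function(g_i, g_j, n_streamlines) {
  if (any(g_i < 1) || any(g_j < 1)) {
    abort("Voxel counts must be >= 1.", class = "connectofuse_invalid_parameter")
  }
  if (any(n_streamlines < 0)) {
    abort("Streamline counts must be >= 0.", class = "connectofuse_invalid_parameter")
  }
  2 / (g_i + g_j) * n_streamlines
}

#' Euclidean centroid-distance matrix
#'
#' Dense symmetric matrix of pairwise Euclidean distances between ROI
#' centroids, in the geometry's native space.
#'
#' @param geometry ROI geometry tibble (`label`, `x`, `y`, `z`, `voxels`).
#' @return Weighted network matrix (distances in mm).
#' @export
ed_matrix <- function(geometry) {
  geometry <- validate_roi_geometry(geometry)
  if (nrow(geometry) < 2) {
    abort("Need at least 2 ROIs.", class = "connectofuse_invalid_parameter")
  }
  D <- as.matrix(dist(as.matrix(geometry[, c("x", "y", "z")])))
  as_weighted_network(D, labels = geometry$label)
}

#' Build the nine NWS connectivity matrices for one scan
#'
#' Aggregates a (length-filtered) tract table into nine symmetric
#' zero-diagonal matrices over the geometry's ROIs:
#' * `NSTR[i,j]`: summed streamline count over records for the pair;
#' * `PSTR`: `NSTR` divided by the whole-brain total (upper-triangle sum 1);
#' * `FA`/`MD`/`RD`/`ATL`: streamline-count-weighted mean of the per-record
#'   metric;
#' * `TV`: summed tract volume;
#' * `SD`: [sd_weight()] applied to `NSTR` and the ROI voxel counts;
#' * `ED`: [ed_matrix()] of the geometry (dense, independent of the tracts).
#'
#' @param tracts Tract table for a single scan.
#' @param geometry ROI geometry.
#' @param l_mm White-matter length threshold applied first (default 0).
#' @return Object of class `"nws_stack"`: named list of the nine matrices plus
#'   `scan_id` / `subject_id` attributes.
#' @export
build_nws <- function(tracts, geometry, l_mm = 0) {
  geometry <- validate_roi_geometry(geometry)
  n <- nrow(geometry)
  tracts <- length_filter(tracts, l_mm)
  if (nrow(tracts) == 0) {
    abort("No tract records survive the length filter; networks are empty.",
      class = "connectofuse_empty_network"
    )
  }
  if (any(tracts$roi_i < 1 | tracts$roi_i > n | tracts$roi_j < 1 | tracts$roi_j > n)) {
    abort("ROI index out of range for the supplied geometry.",
      class = "connectofuse_invalid_parameter"
    )
  }
  if (any(tracts$roi_i == tracts$roi_j)) {
    abort("Self-connections (roi_i == roi_j) are not allowed.",
      class = "connectofuse_invalid_parameter"
    )
  }
  labels <- geometry$label
  scan_id <- unique(tracts$scan_id)
  subject_id <- unique(tracts$subject_id)
  if (length(scan_id) > 1) {
    abort("`build_nws()` expects records from a single scan.",
      class = "connectofuse_invalid_parameter"
    )
  }

  # canonical undirected pair key (i < j)
  i <- pmin(tracts$roi_i, tracts$roi_j)
  j <- pmax(tracts$roi_i, tracts$roi_j)
  key <- (i - 1) * n + j
  cnt <- tracts$n_streamlines

  acc <- function(x) {
    v <- rowsum(x, key)
    list(key = as.numeric(rownames(v)), val = v[, 1])
  }
  nstr <- acc(cnt)
  tv <- acc(tracts$tract_volume_mm3)
  wmean <- function(x) acc(x * cnt)$val / nstr$val

  fill <- function(vals) {
    M <- matrix(0, n, n)
    ii <- floor((nstr$key - 1) / n) + 1
    jj <- nstr$key - (ii - 1) * n
    M[cbind(ii, jj)] <- vals
    M[cbind(jj, ii)] <- vals
    as_weighted_network(M, labels = labels)
  }

  NSTR <- fill(nstr$val)
  total_nstr <- sum(NSTR[upper.tri(NSTR)])
  g <- geometry$voxels
  SD <- NSTR * outer(g, g, function(a, b) 2 / (a + b))
  diag(SD) <- 0

  stack <- list(
    FA = fill(wmean(tracts$mean_fa)),
    MD = fill(wmean(tracts$mean_md)),
    RD = fill(wmean(tracts$mean_rd)),
    ATL = fill(wmean(tracts$mean_length_mm)),
    ED = ed_matrix(geometry),
    SD = as_weighted_network(SD, labels = labels),
    TV = fill(tv$val),
    NSTR = NSTR,
    PSTR = as_weighted_network(NSTR / total_nstr, labels = labels)
  )
  stack <- stack[nws_names()]
  structure(stack,
    class = "nws_stack",
    scan_id = scan_id %||% NA_character_,
    subject_id = subject_id %||% NA_character_,
    l_mm = l_mm
  )
}

#' @export
print.nws_stack <- function(x, ...) {
  cat(sprintf(
    "<nws_stack> scan %s (subject %s): %d ROIs, 9 weightings [%s]\n",
    attr(x, "scan_id"), attr(x, "subject_id"), nrow(x[[1]]),
    paste(names(x), collapse = ", ")
  ))
  invisible(x)
}

#' Write an NWS stack as one CSV matrix per weighting
#' @param stack `"nws_stack"` object.
#' @param dir Output directory; files are named `{scan_id}.{NWS}.csv`.
#' @return `dir`, invisibly.
#' @export
write_nws <- function(stack, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  scan <- attr(stack, "scan_id")
  for (nm in names(stack)) {
    write_matrix(stack[[nm]], file.path(dir, paste0(scan, ".", nm, ".csv")))
  }
  invisible(dir)
}
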