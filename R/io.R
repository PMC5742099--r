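#' Read a labelled square connectivity matrix from CSV
#'
#' Expects a square numeric matrix with node labels both as a header row and as
#' a first column (the format [write_matrix()] produces). The matrix must be
#' symmetric within `1e-9` relative tolerance; tiny asymmetries from decimal
#' round-trips are symmetrised by averaging with a warning.
#'
#' @param path File path.
#' @return A labelled symmetric numeric matrix.
#' @export
read_matrix <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, row.names = 1)
  M <- as.matrix(df)
  if (nrow(M) != ncol(M)) {
    abort(sprintf("Matrix in '%s' is not square (%d x %d).", path, nrow(M), ncol(M)),
      class = "connectofuse_io_error"
    )
  }
  storage.mode(M) <- "double"
  as_weighted_network(M, labels = rownames(M))
}

#' Write a labelled square connectivity matrix to CSV
#'
#' Floats are serialised with 12 significant digits so that
#' `read_matrix(write_matrix(W, f))` round-trips to that precision.
#'
#' @param W Weighted network matrix (validated first).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(W, path) {
  W <- as_weighted_network(W)
  df <- as.data.frame(signif(W, 12))
  utils::write.csv(df, path, row.names = TRUE)
  invisible(path)
}

#' Write a tract table to CSV
#'
#' Fixed column order:
#' `scan_id,subject_id,roi_i,roi_j,n_streamlines,mean_length_mm,wm_length_mm,tract_volume_mm3,mean_fa,mean_md,mean_rd`.
#'
#' @param tracts Tract-table tibble (see [generate_cohort()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tract_table <- function(tracts, path) {
  cols <- c(
    "scan_id", "subject_id", "roi_i", "roi_j", "n_streamlines",
    "mean_length_mm", "wm_length_mm", "tract_volume_mm3",
    "mean_fa", "mean_md", "mean_rd"
  )
  missing <- setdiff(cols, names(tracts))
  if (length(missing) > 0) {
    abort(paste0("Tract table is missing columns: ", paste(missing, collapse = ", ")),
      class = "connectofuse_io_error"
    )
  }
  readr::write_csv(tracts[, cols], path)
  invisible(path)
}

#' Read a tract table from CSV
#' @param path File path.
#' @return Tibble with the fixed tract-table columns.
#' @export
read_tract_table <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}

#' Write / read ROI geometry (label,x,y,z,voxels)
#' @param geometry ROI geometry tibble (see [generate_roi_geometry()]).
#' @param path File path.
#' @return `path` (write) or the geometry tibble (read).
#' @export
write_roi_geometry <- function(geometry, path) {
  readr::write_csv(geometry[, c("label", "x", "y", "z", "voxels")], path)
  invisible(path)
}

#' @rdname write_roi_geometry
#' @export
read_roi_geometry <- function(path) {
  geom <- readr::read_csv(path, show_col_types = FALSE)
  validate_roi_geometry(geom)
}
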