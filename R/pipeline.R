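# End-to-end orchestration: tract tables -> NWS stacks -> fused networks ->
# topological filtering -> metrics, reliability and fingerprinting.

#' Run the full fusion-and-evaluation pipeline on a cohort
#'
#' For every scan: build the nine weighting matrices, fuse them into an
#' integrated network (dissimilarity-derived weights), and topologically
#' filter the fusion at the global-cost-efficiency peak. Across scans: network
#' metrics per variant, ICC reliability, diffusion-distance matrices over all
#' scans for both the fused and the filtered variant, leave-one-out k-NN scan
#' recognition, the quality-of-clustering index, and a 3D MDS embedding.
#'
#' @param cohort `"cohort"` object from [generate_cohort()], or a list with
#'   `tracts` and `geometry` in the same shape.
#' @param l_mm White-matter length threshold for tract filtering (default 0).
#' @param prescale,normalization Scaling modes for fusion and gDDM.
#' @param k Neighbours for recognition (default 4).
#' @param icc_form ICC form (default `"1_1"`).
#' @param variants Which network variants to carry through metrics/ICC;
#'   defaults to the fused and filtered networks plus the raw NSTR weighting.
#' @param metrics Compute network metrics and ICC tables (default TRUE).
#'   Node-level efficiency on dense 90-node graphs dominates runtime, so
#'   fingerprinting-only studies can switch this off.
#' @return List of class `"cohort_fit"`: per-scan objects (`stacks`, `fused`,
#'   `filtered`), `metrics`, `icc`, `dissimilarity` (per variant),
#'   `recognition` (per variant), `qci` (per variant), `embedding`, and the
#'   scan bookkeeping table `scans`.
#' @export
cohort_pipeline <- function(cohort, l_mm = 0,
                            prescale = "max", normalization = "max",
                            k = 4, icc_form = "1_1",
                            variants = c("IWSBN", "IWSBN_TF", "NSTR"),
                            metrics = TRUE) {
  tracts <- cohort$tracts
  geometry <- cohort$geometry
  scans <- dplyr::distinct(tracts, .data$subject_id, .data$scan_id)

  stacks <- purrr::map(seq_len(nrow(scans)), function(r) {
    build_nws(
      dplyr::filter(tracts, .data$scan_id == scans$scan_id[r]),
      geometry,
      l_mm = l_mm
    )
  })
  names(stacks) <- scans$scan_id

  fused <- purrr::map(stacks, integrate_nws,
    prescale = prescale, normalization = normalization
  )
  filtered <- purrr::map(fused, function(f) omst_filter(f$W))

  nets_by_variant <- list(
    IWSBN = purrr::map(fused, "W"),
    IWSBN_TF = purrr::map(filtered, "filtered"),
    NSTR = purrr::map(stacks, "NSTR")
  )[variants]

  if (isTRUE(metrics)) {
    metrics_tbl <- purrr::imap_dfr(nets_by_variant, function(nets, vn) {
      purrr::imap_dfr(nets, function(W, sid) {
        network_metrics(W,
          scan_id = sid,
          subject_id = scans$subject_id[match(sid, scans$scan_id)],
          variant = vn
        )
      })
    })
    icc_tbl <- icc_report(metrics_tbl, form = icc_form)
  } else {
    metrics_tbl <- NULL
    icc_tbl <- NULL
  }

  dissimilarity <- purrr::map(nets_by_variant, pairwise_dissimilarity,
    normalization = normalization
  )
  recognition <- purrr::map(dissimilarity, function(ds) {
    knn_recognition(ds$D, labels = scans$subject_id, k = k)
  })
  qci_tbl <- tibble::tibble(
    variant = names(dissimilarity),
    qci = vapply(dissimilarity, function(ds) qci(ds$D, scans$subject_id), numeric(1))
  )
  embedding <- mds_embed(dissimilarity[[1]]$D, dims = 3, labels = scans$scan_id)

  structure(
    list(
      scans = scans,
      stacks = stacks,
      fused = fused,
      filtered = filtered,
      metrics = metrics_tbl,
      icc = icc_tbl,
      dissimilarity = dissimilarity,
      recognition = recognition,
      qci = qci_tbl,
      embedding = embedding,
      options = list(
        l_mm = l_mm, prescale = prescale, normalization = normalization,
        k = k, icc_form = icc_form
      )
    ),
    class = "cohort_fit"
  )
}

#' @export
print.cohort_fit <- function(x, ...) {
  cat(sprintf(
    "<cohort_fit> %d scans, %d subjects\n",
    nrow(x$scans), length(unique(x$scans$subject_id))
  ))
  for (vn in names(x$recognition)) {
    cat(sprintf(
      "  %-8s recognition accuracy %.3f (k = %d), QCI %.3f\n",
      vn, x$recognition[[vn]]$accuracy, x$recognition[[vn]]$k,
      x$qci$qci[x$qci$variant == vn]
    ))
  }
  invisible(x)
}

#' @export
glance.cohort_fit <- function(x, ...) {
  tibble::tibble(
    variant = names(x$recognition),
    accuracy = vapply(x$recognition, `[[`, numeric(1), "accuracy"),
    qci = x$qci$qci[match(names(x$recognition), x$qci$variant)],
    mean_icc_ge = vapply(names(x$recognition), function(vn) {
      if (is.null(x$icc)) {
        return(NA_real_)
      }
      mean(x$icc$icc[x$icc$variant == vn & x$icc$metric == "global_efficiency"])
    }, numeric(1))
  )
}

#' Write the main pipeline outputs to a directory
#'
#' Metrics and ICC tables as CSV, recognition and QCI as JSON, the filtered
#' matrices as CSVs, the embedding as CSV, plus a JSON run log with the
#' pipeline options.
#'
#' @param fit `"cohort_fit"` object.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_cohort_fit <- function(fit, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(fit$metrics)) {
    readr::write_csv(fit$metrics, file.path(dir, "metrics.csv"))
    readr::write_csv(fit$icc, file.path(dir, "icc.csv"))
  }
  readr::write_csv(fit$embedding, file.path(dir, "embedding.csv"))
  jsonlite::write_json(
    list(
      qci = stats::setNames(as.list(fit$qci$qci), fit$qci$variant),
      recognition = lapply(fit$recognition, function(r) {
        list(accuracy = r$accuracy, k = r$k)
      }),
      options = fit$options
    ),
    file.path(dir, "report.json"),
    auto_unbox = TRUE, digits = NA
  )
  for (sid in names(fit$filtered)) {
    write_matrix(
      fit$filtered[[sid]]$filtered,
      file.path(dir, paste0(sid, ".IWSBN_TF.csv"))
    )
  }
  invisible(dir)
}
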