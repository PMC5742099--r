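# Synthetic multi-subject, multi-scan cohorts
#
# The generator emulates a test-retest tractography design: each subject owns a
# latent connection-strength matrix (distance-decaying baseline modulated by a
# subject-specific module structure and a per-edge fingerprint), and each scan
# redraws streamline counts and tract metrics around the subject-level means
# with scan-level noise. Nothing here simulates the DWI signal or tractography;
# the output starts at the tract-table level.

validate_roi_geometry <- function(geometry) {
  need <- c("label", "x", "y", "z", "voxels")
  missing <- setdiff(need, names(geometry))
  if (length(missing) > 0) {
    abort(paste0("ROI geometry is missing columns: ", paste(missing, collapse = ", ")),
      class = "connectofuse_invalid_parameter"
    )
  }
  if (anyDuplicated(geometry$label) > 0) {
    abort("ROI labels must be unique.", class = "connectofuse_invalid_parameter")
  }
  if (any(!is.finite(as.matrix(geometry[, c("x", "y", "z")])))) {
    abort("ROI centroids must be finite.", class = "connectofuse_invalid_parameter")
  }
  if (any(geometry$voxels < 1)) {
    abort("ROI voxel counts must be >= 1.", class = "connectofuse_invalid_parameter")
  }
  geometry
}

#' Generate synthetic ROI geometry
#'
#' Samples `n_rois` centroids uniformly inside a brain-sized bounding box
#' (140 x 170 x 120 mm) and gray-matter voxel counts from a log-normal
#' distribution (median about 1800 voxels, matching coarse anatomical
#' parcellations at 1 mm resolution).
#'
#' @param n_rois Number of regions (>= 3).
#' @param seed Integer seed; the call is deterministic given the seed.
#' @return Tibble with columns `label`, `x`, `y`, `z` (mm), `voxels`.
#' @export
generate_roi_geometry <- function(n_rois, seed = 1L) {
  if (!is.numeric(n_rois) || n_rois < 3) {
    abort("`n_rois` must be at least 3.", class = "connectofuse_invalid_parameter")
  }
  n_rois <- as.integer(n_rois)
  with_local_seed(seed, {
    geom <- tibble::tibble(
      label = sprintf("roi_%03d", seq_len(n_rois)),
      x = runif(n_rois, -70, 70),
      y = runif(n_rois, -100, 70),
      z = runif(n_rois, -50, 70),
      voxels = pmax(1L, as.integer(round(rlnorm(n_rois, meanlog = log(1800), sdlog = 0.5))))
    )
    validate_roi_geometry(geom)
  })
}

#' Cohort generator parameters
#'
#' @param lambda_mm Length scale (mm) of the distance-decaying baseline
#'   connection strength `exp(-d/lambda)`.
#' @param base_count Expected streamline count of the strongest (zero-distance)
#'   connection before modulation.
#' @param n_modules Number of modules in the subject-specific planted
#'   partition.
#' @param module_boost Multiplicative boost of within-module connection means
#'   (between-subject effect size; subjects differ in module assignment).
#' @param fingerprint_sd Standard deviation (log scale) of the subject-specific
#'   per-edge multiplier — the stable "fingerprint" that makes scans of one
#'   subject resemble each other more than scans of different subjects.
#' @param nb_size Negative-binomial size (inverse overdispersion) of the
#'   per-scan streamline counts.
#' @param scan_noise Scan-level noise scale: log-sd of the multiplicative
#'   drift on count means, lengths and volumes; 0 switches off all scan-level
#'   count randomness, giving identical count matrices across scans.
#' @param measurement_noise Additive scan-level noise sd on FA (and scaled
#'   noise on MD/RD).
#' @return Named list of parameters.
#' @export
cohort_params <- function(lambda_mm = 40,
                          base_count = 120,
                          n_modules = 6,
                          module_boost = 1.0,
                          fingerprint_sd = 0.4,
                          nb_size = 8,
                          scan_noise = 0.1,
                          measurement_noise = 0.02) {
  p <- list(
    lambda_mm = lambda_mm, base_count = base_count, n_modules = n_modules,
    module_boost = module_boost, fingerprint_sd = fingerprint_sd,
    nb_size = nb_size, scan_noise = scan_noise,
    measurement_noise = measurement_noise
  )
  if (p$scan_noise < 0 || p$measurement_noise < 0 || p$fingerprint_sd < 0) {
    abort("Noise scales must be nonnegative.", class = "connectofuse_invalid_parameter")
  }
  if (p$lambda_mm <= 0 || p$base_count <= 0 || p$nb_size <= 0) {
    abort("`lambda_mm`, `base_count` and `nb_size` must be positive.",
      class = "connectofuse_invalid_parameter"
    )
  }
  p
}

#' Generate a synthetic test-retest cohort of tract tables
#'
#' Latent model, per subject: a connection-mean matrix
#' `mu_ij = base_count * exp(-d_ij / lambda) * (1 + module_boost * same_module_ij) * f_ij`,
#' where `d_ij` is the centroid Euclidean distance, the module assignment is a
#' subject-specific random partition into `n_modules` groups, and `f_ij` is a
#' subject-specific log-normal per-edge fingerprint. Per scan, streamline
#' counts are drawn from a negative binomial around the subject mean (with a
#' multiplicative log-normal drift of scale `scan_noise`), so weak
#' connections flip in and out between repeat scans the way real streamline
#' counts do; `scan_noise = 0` is the degenerate noise-free case with
#' deterministic counts. Edges whose scan count is zero are absent from that
#' scan's table. Tract metrics: `mean_length_mm` is the centroid distance
#' times a curvature factor; `wm_length_mm` is `mean_length_mm` minus a
#' positive offset (a Beta-distributed fraction of the length), placing a
#' graded share of records under a 0-6 mm white-matter length sweep;
#' `tract_volume_mm3` scales with count x length; FA/MD/RD are subject-level
#' truncated Gaussians per tract with additive scan noise (FA clipped to
#' the unit interval, diffusivities kept positive).
#'
#' @param n_subjects,n_scans Design size (both >= 2).
#' @param geometry ROI geometry from [generate_roi_geometry()].
#' @param params Parameter list from [cohort_params()].
#' @param seed Integer seed; tables are byte-identical given the seed.
#' @return List of class `"cohort"` with elements `tracts` (one tibble, all
#'   scans, tract-table columns), `manifest` (subject/scan ids, n_rois, seed,
#'   params) and `geometry`.
#' @export
generate_cohort <- function(n_subjects, n_scans, geometry,
                            params = cohort_params(), seed = 1L) {
  if (n_subjects < 2 || n_scans < 2) {
    abort("Need at least 2 subjects and 2 scans.", class = "connectofuse_invalid_parameter")
  }
  params <- do.call(cohort_params, params[names(params) %in% names(formals(cohort_params))])
  geometry <- validate_roi_geometry(geometry)
  n <- nrow(geometry)
  xyz <- as.matrix(geometry[, c("x", "y", "z")])
  d <- as.matrix(dist(xyz))
  ut <- which(upper.tri(d), arr.ind = TRUE)
  pair_i <- ut[, 1]
  pair_j <- ut[, 2]
  d_pair <- d[ut]

  subject_ids <- sprintf("sub_%02d", seq_len(n_subjects))
  scan_ids <- sprintf("scan_%02d", seq_len(n_scans))

  tracts <- with_local_seed(seed, {
    purrr::map_dfr(seq_len(n_subjects), function(s) {
      modules <- sample(rep_len(seq_len(params$n_modules), n))
      same_mod <- modules[pair_i] == modules[pair_j]
      fingerprint <- rlnorm(length(d_pair), -params$fingerprint_sd^2 / 2, params$fingerprint_sd)
      mu <- params$base_count * exp(-d_pair / params$lambda_mm) *
        (1 + params$module_boost * same_mod) * fingerprint

      # subject-level tract geometry and tensor metrics (stable across scans)
      curvature <- runif(length(d_pair), 1.1, 1.6)
      mean_len <- pmax(d_pair, 1) * curvature
      # retained white-matter fraction of each tract's length; small so that a
      # 0-6 mm minimum-WM-length sweep removes a graded share of records
      wm_keep <- stats::rbeta(length(d_pair), 1, 6)
      fa_sub <- pmin(1, pmax(0, rnorm(length(d_pair), 0.45, 0.1)))
      md_sub <- pmax(1e-4, rnorm(length(d_pair), 8e-4, 1e-4))
      rd_sub <- pmax(1e-4, rnorm(length(d_pair), 6e-4, 1e-4))

      purrr::map_dfr(seq_len(n_scans), function(sc) {
        # per-scan counting noise: negative binomial around the subject mean,
        # so weak connections flip in and out between scans the way real
        # streamline counts do; zero scan noise is the stated degenerate case
        # with noise-free (deterministic) counts
        counts <- if (params$scan_noise > 0) {
          drift <- rlnorm(length(mu), -params$scan_noise^2 / 2, params$scan_noise)
          as.integer(rnbinom(length(mu), size = params$nb_size, mu = mu * drift))
        } else {
          as.integer(round(mu))
        }
        keep <- counts >= 1
        mnoise <- params$measurement_noise * rnorm(length(mu))
        len_sc <- mean_len * (if (params$scan_noise > 0) {
          rlnorm(length(mu), -params$scan_noise^2 / 2, params$scan_noise / 2)
        } else {
          rep(1, length(mu))
        })
        wm_sc <- pmax(0.1, len_sc * wm_keep - 0.5)
        tibble::tibble(
          scan_id = paste0(subject_ids[s], ".", scan_ids[sc]),
          subject_id = subject_ids[s],
          roi_i = pair_i[keep],
          roi_j = pair_j[keep],
          n_streamlines = counts[keep],
          mean_length_mm = len_sc[keep],
          wm_length_mm = wm_sc[keep],
          tract_volume_mm3 = 2 * counts[keep] * len_sc[keep] /
            pmax(1, sqrt(counts[keep])),
          mean_fa = pmin(1, pmax(0, fa_sub + mnoise))[keep],
          mean_md = pmax(1e-5, md_sub + 1e-3 * mnoise)[keep],
          mean_rd = pmax(1e-5, rd_sub + 1e-3 * mnoise)[keep]
        )
      })
    })
  })

  structure(
    list(
      tracts = tracts,
      manifest = list(
        subject_ids = subject_ids,
        scan_ids = scan_ids,
        n_rois = n,
        seed = as.integer(seed),
        params = params
      ),
      geometry = geometry
    ),
    class = "cohort"
  )
}

#' @export
print.cohort <- function(x, ...) {
  m <- x$manifest
  cat(sprintf(
    "<cohort> %d subjects x %d scans, %d ROIs, %d tract records (seed %d)\n",
    length(m$subject_ids), length(m$scan_ids), m$n_rois, nrow(x$tracts), m$seed
  ))
  invisible(x)
}

#' Save a cohort to a directory (tract-table CSVs, geometry CSV, manifest JSON)
#' @param cohort A `"cohort"` object.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_tract_table(cohort$tracts, file.path(dir, "tracts.csv"))
  write_roi_geometry(cohort$geometry, file.path(dir, "geometry.csv"))
  jsonlite::write_json(cohort$manifest, file.path(dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}

# run code under a temporary RNG state; restores the caller's state after
with_local_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed) %% .Machine$integer.max)
  force(code)
}

# derive a per-stage seed from a master seed; keeps values in 32-bit range
derive_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647L)
}
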