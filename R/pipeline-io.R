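# Format plumbing and orchestration: NIfTI volumes and maps (RNifti),
# PNG masks, CSV tables, JSON manifests/reports, and the end-to-end
# pipeline simulate -> metrics -> biometrics -> cohort stats ->
# two-stage association -> report.

#' Save a 4D volume or 3D metric map as NIfTI-1
#'
#' Data, affine (sform, code 2), and TR (pixdim(4) for 4D series) are
#' preserved losslessly (double-precision datatype).
#'
#' @param x A [voxel_volume()] or [metric_map()].
#' @param path Output file path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
save_volume <- function(x, path) {
  if (inherits(x, "voxel_volume")) {
    img <- RNifti::asNifti(x$data)
    RNifti::sform(img) <- structure(x$affine, code = 2L)
    pd <- RNifti::pixdim(img)
    pd[4L] <- x$tr
    RNifti::pixdim(img) <- pd
  } else if (inherits(x, "metric_map")) {
    img <- RNifti::asNifti(x$data)
    RNifti::sform(img) <- structure(x$affine, code = 2L)
  } else stop("save_volume: expected a voxel_volume or metric_map",
              call. = FALSE)
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}

#' Load a NIfTI file as a volume or metric map
#'
#' @param path NIfTI file path.
#' @param as `"auto"` (by dimensionality), `"volume"` (4D series, error if
#'   the file is not 4D), or `"map"` (3D).
#' @param tr Repetition time override in seconds; by default read from
#'   `pixdim(4)`.
#' @return A [voxel_volume()] or [metric_map()].
#' @export
load_volume <- function(path, as = c("auto", "volume", "map"), tr = NULL) {
  as <- match.arg(as)
  if (!file.exists(path))
    stop(sprintf("load_volume: file not found: %s", path), call. = FALSE)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e)
                    stop(sprintf("load_volume: malformed NIfTI '%s': %s",
                                 path, conditionMessage(e)), call. = FALSE))
  data <- array(as.numeric(img), dim = dim(img))
  nd <- length(dim(data))
  affine <- matrix(as.numeric(RNifti::xform(img)), 4L, 4L)
  if (as == "volume" || (as == "auto" && nd == 4L)) {
    if (nd != 4L)
      stop(sprintf("load_volume: %s is %dD, expected a 4D series", path, nd),
           call. = FALSE)
    if (is.null(tr)) tr <- RNifti::pixdim(img)[4L]
    voxel_volume(data, affine, tr)
  } else {
    if (nd != 3L)
      stop(sprintf("load_volume: %s is %dD, expected a 3D map", path, nd),
           call. = FALSE)
    metric_map(data, affine, metric = basename(path))
  }
}

#' Save / load a binary mask as PNG
#'
#' 8-bit grayscale; nonzero pixels are foreground.
#'
#' @param mask Logical matrix.
#' @param path PNG file path.
#' @return `path` invisibly; [load_mask_png()] returns a logical matrix.
#' @export
save_mask_png <- function(mask, path) {
  png::writePNG(as_mask(mask) * 1, path)
  invisible(path)
}

#' @rdname save_mask_png
#' @export
load_mask_png <- function(path) {
  m <- png::readPNG(path)
  if (length(dim(m)) == 3L) m <- m[, , 1L]
  as_mask(m > 0)
}

#' Run configuration for the full pipeline
#'
#' @param cohort A [cohort_config()].
#' @param gm_threshold Group gray-matter mask threshold (default 0.2).
#' @param band fMRI frequency band, Hz.
#' @param fwhm_mm Smoothing FWHM for the metric maps (default 0: the 4 mm
#'   kernel is the convention for the thickness channel, exposed for all).
#' @param alpha Voxel-wise FWE level.
#' @param n_perm Permutations for the voxel-wise FWE.
#' @param pairs List of group pairs for the association scans.
#' @param scores,biometrics Column selections for the scans.
#' @param channels Brain channels to run (`"falff"`, `"reho"`,
#'   `"thickness"`).
#' @param out_dir Output directory, or `NULL` for in-memory only.
#' @param seed Association-stage seed (the cohort uses `cohort$seed`).
#' @return Object of class `run_config`.
#' @export
run_config <- function(cohort = cohort_config(), gm_threshold = 0.2,
                       band = c(0.01, 0.1), fwhm_mm = 0, alpha = 0.05,
                       n_perm = 1000,
                       pairs = list(c("HC", "SCD"), c("HC", "MCI"),
                                    c("HC", "AD")),
                       scores = c("MMSE", "MoCA", "BNT", "CDT", "BDST",
                                  "TMT_A", "TMT_B"),
                       biometrics = c("faz_area_mm2", "faz_perimeter_mm",
                                      "rbvc_per_px", "rnfl_um",
                                      "gcl_ipl_um"),
                       channels = c("falff", "reho", "thickness"),
                       out_dir = NULL, seed = 1) {
  stopifnot(inherits(cohort, "cohort_config"))
  if (gm_threshold < 0 || gm_threshold > 1)
    stop_config("gm_threshold", "must be in [0, 1]")
  if (alpha <= 0 || alpha > 1) stop_config("alpha", "must be in (0, 1]")
  structure(list(cohort = cohort, gm_threshold = gm_threshold, band = band,
                 fwhm_mm = fwhm_mm, alpha = alpha, n_perm = n_perm,
                 pairs = pairs, scores = scores, biometrics = biometrics,
                 channels = channels, out_dir = out_dir, seed = seed),
            class = "run_config")
}

#' Per-subject brain metric matrices for a cohort
#'
#' Generates (or consumes) each subject's fMRI run, computes the
#' standardized metric maps, builds the group gray-matter mask, and
#' returns subject x voxel matrices restricted to that mask.
#'
#' @param config A [cohort_config()].
#' @param subjects The [generate_cohort()] table.
#' @param channels Any of `"falff"`, `"reho"`.
#' @param gm_threshold Group-mask threshold on the mean GM probability.
#' @param band Frequency band, Hz.
#' @param fwhm_mm Smoothing FWHM, mm.
#' @return List: `falff`/`reho` (n x V matrices), `gm_mask`, `voxel_idx`,
#'   `affine`.
#' @export
cohort_brain_maps <- function(config, subjects, channels = c("falff", "reho"),
                              gm_threshold = 0.2, band = c(0.01, 0.1),
                              fwhm_mm = 0) {
  n <- nrow(subjects)
  gm_list <- vector("list", n)
  maps <- list()
  affine <- NULL
  for (i in seq_len(n)) {
    fm <- generate_fmri(subjects[i, ], config)
    gm_list[[i]] <- fm$gm_prob
    res <- process_fmri_subject(fm$volume, fm$motion,
                                brain_mask = fm$gm_prob >= 0.5,
                                n_discard = config$grid_shape$n_discard,
                                band = band, fwhm_mm = fwhm_mm,
                                voxel_size_mm = config$grid_shape$voxel_mm,
                                channels = channels)
    affine <- fm$volume$affine
    for (ch in names(res)) maps[[ch]][[i]] <- res[[ch]]
  }
  gm_mask <- build_group_gm_mask(gm_list, gm_threshold)
  voxel_idx <- which(gm_mask)
  out <- list(gm_mask = gm_mask, voxel_idx = voxel_idx, affine = affine)
  for (ch in names(maps))
    out[[ch]] <- do.call(rbind, lapply(maps[[ch]],
                                       function(m) m$data[voxel_idx]))
  out
}

#' Measured ophthalmic biometrics for a cohort
#'
#' Generates each subject's retinal image set and measures the biometrics
#' from the images (not from the planted targets).
#'
#' @param config A [cohort_config()].
#' @param subjects The [generate_cohort()] table.
#' @param min_area_px Small-object cleanup threshold.
#' @param measure_rbvc Compute centerline curvature (the slowest
#'   biometric); when `FALSE`, `rbvc_*` columns are `NA`.
#' @return Data frame, one row per subject, [retinal_biometrics()] columns.
#' @export
cohort_retina_biometrics <- function(config, subjects, min_area_px = 5,
                                     measure_rbvc = TRUE) {
  rows <- lapply(seq_len(nrow(subjects)), function(i) {
    img <- generate_retina(subjects[i, ], config)
    if (measure_rbvc) {
      retinal_biometrics(img, min_area_px = min_area_px)
    } else {
      # one labeling pass serves cleanup, area, and perimeter
      lab <- label_components(img$faz_mask)
      sizes <- tabulate(lab[lab > 0])
      if (!length(sizes) || max(sizes) < max(1, min_area_px))
        stop("cohort_retina_biometrics: no FAZ region", call. = FALSE)
      comp <- lab == which.max(sizes)
      pts <- rbind(trace_boundary(comp), trace_boundary(comp)[1, ])
      data.frame(faz_area_mm2 = sum(comp) * img$pixel_size_mm^2,
                 faz_perimeter_mm = sum(sqrt(rowSums(diff(pts)^2))) *
                   img$pixel_size_mm,
                 rbvc_per_px = NA_real_, rbvc_per_mm = NA_real_,
                 rnfl_um = layer_thickness_mean(img$thickness_maps$RNFL),
                 gcl_ipl_um = layer_thickness_mean(img$thickness_maps$GCL_IPL),
                 quality_pass = quality_gate(img))
    }
  })
  do.call(rbind, rows)
}

#' DKT thickness matrix for a cohort
#'
#' @param config A [cohort_config()].
#' @param subjects The [generate_cohort()] table.
#' @return n x 62 matrix with DKT labels as column names.
#' @export
cohort_thickness_matrix <- function(config, subjects) {
  do.call(rbind, lapply(seq_len(nrow(subjects)), function(i)
    generate_thickness_table(subjects[i, ], config)))
}

#' Run the full pipeline on a synthetic cohort
#'
#' simulate -> fMRI metrics -> retinal biometrics -> DKT thickness ->
#' demographics table -> two-stage association per configured group pair.
#' Deterministic given the configuration (all randomness flows from
#' `cohort$seed` and `seed`). When `out_dir` is set, writes the subjects
#' and biometrics CSVs, the cohort-stats CSV, and a JSON report.
#'
#' @param rc A [run_config()].
#' @return List of class `run_report`: `subjects` (with measured
#'   biometrics merged), `cohort_stats`, `gm_mask`, per-channel matrices,
#'   `associations` (per pair), `files` (paths written), and provenance.
#' @export
run_full_pipeline <- function(rc) {
  stopifnot(inherits(rc, "run_config"))
  config <- rc$cohort
  subjects <- generate_cohort(config)
  vox_channels <- intersect(rc$channels, c("falff", "reho"))
  brain <- if (length(vox_channels))
    cohort_brain_maps(config, subjects, vox_channels, rc$gm_threshold,
                      rc$band, rc$fwhm_mm)
  else list(gm_mask = NULL, voxel_idx = NULL)
  bio <- cohort_retina_biometrics(config, subjects)
  subjects_measured <- cbind(
    subjects[, setdiff(names(subjects), names(bio))], bio)
  thick <- if ("thickness" %in% rc$channels)
    cohort_thickness_matrix(config, subjects) else NULL
  stats_tab <- cohort_stats_table(subjects_measured, rc$scores)
  associations <- list()
  for (pair in rc$pairs) {
    key <- paste(pair, collapse = "_")
    associations[[key]] <- run_group_pair_analysis(
      subjects_measured,
      falff = if ("falff" %in% names(brain)) brain$falff else NULL,
      reho = if ("reho" %in% names(brain)) brain$reho else NULL,
      thickness = thick, pair = pair, scores = rc$scores,
      biometrics = rc$biometrics, alpha = rc$alpha, n_perm = rc$n_perm,
      seed = rc$seed)
  }
  report <- structure(
    list(subjects = subjects_measured, cohort_stats = stats_tab,
         gm_mask = brain$gm_mask, voxel_idx = brain$voxel_idx,
         falff = brain$falff, reho = brain$reho, thickness = thick,
         associations = associations,
         provenance = list(seed = config$seed, assoc_seed = rc$seed,
                           n_perm = rc$n_perm, alpha = rc$alpha,
                           gm_threshold = rc$gm_threshold,
                           version = as.character(utils::packageVersion("cebconn"))),
         files = character(0)),
    class = "run_report")
  if (!is.null(rc$out_dir)) {
    dir.create(rc$out_dir, recursive = TRUE, showWarnings = FALSE)
    files <- c(
      subjects = file.path(rc$out_dir, "subjects.csv"),
      cohort_stats = file.path(rc$out_dir, "cohort_stats.csv"),
      report = file.path(rc$out_dir, "report.json"))
    utils::write.csv(subjects_measured, files["subjects"], row.names = FALSE)
    utils::write.csv(stats_tab, files["cohort_stats"], row.names = FALSE)
    jsonlite::write_json(summarize_report(report), files["report"],
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    report$files <- files
  }
  report
}

#' Compact JSON-ready summary of a pipeline report
#'
#' @param report A `run_report` from [run_full_pipeline()].
#' @return Nested list of scalars (counts, peaks, signs) safe to serialize.
#' @export
summarize_report <- function(report) {
  assoc <- lapply(report$associations, function(pr) {
    lapply(pr$results, function(ch) lapply(ch, function(entry) {
      out <- list(stage1_n_selected = entry$stage1_n_selected)
      out$stage2 <- lapply(entry$stage2, function(s2) {
        r <- list(n_selected = s2$n_selected)
        if (!is.null(s2$peak)) {
          r$peak_t <- s2$peak$t
          r$beta1_sign <- s2$beta1_sign
          if (!is.null(s2$peak$label)) r$peak_label <- s2$peak$label
          if (!is.null(s2$peak$voxel)) r$peak_voxel <- s2$peak$voxel
        }
        r
      })
      out
    }))
  })
  list(n_subjects = nrow(report$subjects),
       groups = as.list(table(report$subjects$group)),
       provenance = report$provenance,
       associations = assoc)
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("<run_report> %d subjects; %d association pair(s); %s voxels in GM mask\n",
              nrow(x$subjects), length(x$associations),
              if (is.null(x$voxel_idx)) "no" else length(x$voxel_idx)))
  invisible(x)
}
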