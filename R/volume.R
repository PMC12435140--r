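# Containers for voxel data. Thin S3 lists: a 4D time-series volume
# (data, affine, TR) and a 3D metric map (data, affine, metric name,
# standardized flag). Voxel indices are 1-based in R code; world (mm)
# coordinates follow the NIfTI affine convention applied to 0-based
# indices, matching how NIfTI files store the mapping.

#' 4D voxel time-series volume
#'
#' @param data 4D numeric array (x, y, z, t) with t >= 2.
#' @param affine 4x4 invertible voxel-to-world matrix (applied to 0-based
#'   voxel indices, NIfTI convention).
#' @param tr Repetition time in seconds (> 0).
#' @return Object of class `voxel_volume`.
#' @export
voxel_volume <- function(data, affine = diag(4), tr = 2) {
  if (length(dim(data)) != 4L)
    stop("voxel_volume: data must be a 4D array", call. = FALSE)
  if (dim(data)[4L] < 2L)
    stop("voxel_volume: need at least 2 time points", call. = FALSE)
  assert_scalar_positive(tr, "tr")
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4L, 4L)) || abs(det(affine)) < 1e-12)
    stop("voxel_volume: affine must be an invertible 4x4 matrix", call. = FALSE)
  structure(list(data = data, affine = affine, tr = tr),
            class = "voxel_volume")
}

#' @export
print.voxel_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<voxel_volume> %d x %d x %d grid, %d volumes, TR = %g s\n",
              d[1], d[2], d[3], d[4], x$tr))
  invisible(x)
}

#' 3D metric map
#'
#' @param data 3D numeric array.
#' @param affine 4x4 voxel-to-world matrix.
#' @param metric Metric name, e.g. `"FALFF"`, `"ReHo"`.
#' @param standardized Has the map been divided by its in-mask mean?
#' @return Object of class `metric_map`.
#' @export
metric_map <- function(data, affine = diag(4), metric = "FALFF",
                       standardized = FALSE) {
  if (length(dim(data)) != 3L)
    stop("metric_map: data must be a 3D array", call. = FALSE)
  assert_flag(standardized, "standardized")
  structure(list(data = data, affine = as.matrix(affine), metric = metric,
                 standardized = standardized),
            class = "metric_map")
}

#' @export
print.metric_map <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<metric_map> %s, %d x %d x %d%s\n", x$metric,
              d[1], d[2], d[3],
              if (x$standardized) ", standardized" else ""))
  invisible(x)
}
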