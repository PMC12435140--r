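# Ophthalmic biometrics from OCTA-derived segmentation masks: FAZ area
# and perimeter from the FAZ mask, retinal blood vessel curvature (RBVC)
# from the vessel mask via skeleton centerlines, and mean layer thickness
# (RNFL, GCL-IPL) from thickness maps. Masks are logical matrices in
# (row, col) order; 8-connectivity is used throughout for components,
# boundaries, and skeletons. Pixel area is pixel_size_mm^2.

#' Retinal image set container
#'
#' @param vessel_mask,faz_mask Logical matrices (same shape).
#' @param thickness_maps Named list of numeric matrices in micrometres
#'   (typically `RNFL` and `GCL_IPL`), same shape as the masks.
#' @param pixel_size_mm Pixel edge length in mm (> 0).
#' @param quality_index Scan quality index (device scale; scans below 6
#'   are conventionally excluded).
#' @return Object of class `retinal_image_set`.
#' @export
retinal_image_set <- function(vessel_mask, faz_mask, thickness_maps = list(),
                              pixel_size_mm = 0.01, quality_index = 10) {
  vessel_mask <- as_mask(vessel_mask)
  faz_mask <- as_mask(faz_mask)
  if (!identical(dim(vessel_mask), dim(faz_mask)))
    stop("retinal_image_set: masks must share shape", call. = FALSE)
  for (nm in names(thickness_maps))
    if (!identical(dim(thickness_maps[[nm]]), dim(vessel_mask)))
      stop(sprintf("retinal_image_set: thickness map '%s' shape mismatch", nm),
           call. = FALSE)
  assert_scalar_positive(pixel_size_mm, "pixel_size_mm")
  structure(list(vessel_mask = vessel_mask, faz_mask = faz_mask,
                 thickness_maps = thickness_maps,
                 pixel_size_mm = pixel_size_mm,
                 quality_index = quality_index),
            class = "retinal_image_set")
}

as_mask <- function(m) {
  m <- as.matrix(m)
  matrix(as.logical(m != 0 & !is.na(m)), nrow(m), ncol(m))
}

#' Scan quality gate
#'
#' @param img A [retinal_image_set()].
#' @param min_quality Minimum acceptable quality index (default 6).
#' @return `TRUE` (pass) iff `quality_index >= min_quality`.
#' @export
quality_gate <- function(img, min_quality = 6) {
  stopifnot(inherits(img, "retinal_image_set"))
  img$quality_index >= min_quality
}

#' 8-connected component labeling
#'
#' Labels foreground pixels so that pixels touching by face or corner share
#' a label. (4-connected labeling is run first, then labels of diagonally
#' adjacent components are merged.)
#'
#' @param mask Logical matrix.
#' @return Integer matrix; 0 = background, components numbered from 1.
#' @export
label_components <- function(mask) {
  mask <- as_mask(mask)
  if (!any(mask)) return(matrix(0L, nrow(mask), ncol(mask)))
  lab4 <- EBImage::bwlabel(mask * 1)
  lab4 <- matrix(as.integer(lab4), nrow(mask), ncol(mask))
  nlab <- max(lab4)
  parent <- seq_len(nlab)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  # merge labels that touch diagonally
  for (dd in list(c(1, 1), c(1, -1))) {
    a <- lab4[seq_len(nrow(lab4) - 1), seq_len(ncol(lab4))]
    # pair each pixel with its (dd) diagonal neighbor
    i1 <- seq_len(nrow(lab4) - 1)
    j1 <- if (dd[2] == 1) seq_len(ncol(lab4) - 1) else 2:ncol(lab4)
    j2 <- if (dd[2] == 1) 2:ncol(lab4) else seq_len(ncol(lab4) - 1)
    p <- lab4[i1, j1, drop = FALSE]
    q <- lab4[i1 + 1, j2, drop = FALSE]
    hit <- p > 0 & q > 0 & p != q
    if (any(hit)) {
      pairs <- unique(cbind(p[hit], q[hit]))
      for (r in seq_len(nrow(pairs))) {
        ra <- find(pairs[r, 1]); rb <- find(pairs[r, 2])
        if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
      }
    }
  }
  root <- vapply(seq_len(nlab), find, 1L)
  compact <- match(root, sort(unique(root)))
  out <- lab4
  out[lab4 > 0] <- compact[lab4[lab4 > 0]]
  out
}

#' Remove small connected components
#'
#' Drops 8-connected components with fewer than `min_area_px` pixels —
#' the standard cleanup after vessel/FAZ segmentation.
#'
#' @param mask Logical matrix.
#' @param min_area_px Minimum component size in pixels.
#' @return Cleaned logical matrix.
#' @export
clean_components <- function(mask, min_area_px = 5) {
  mask <- as_mask(mask)
  if (min_area_px <= 0 || !any(mask)) return(mask)
  lab <- label_components(mask)
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= min_area_px)
  lab > 0 & lab %in% keep
}

largest_component <- function(mask, what) {
  lab <- label_components(mask)
  n <- max(lab)
  if (n == 0) stop(sprintf("%s: no region in mask", what), call. = FALSE)
  sizes <- tabulate(lab[lab > 0])
  if (n > 1)
    warning(sprintf("%s: %d components in mask; using the largest", what, n))
  lab == which.max(sizes)
}

#' FAZ area
#'
#' Pixel count of the (largest) FAZ component times the pixel area.
#'
#' @param faz_mask Logical matrix (cleaned FAZ segmentation).
#' @param pixel_size_mm Pixel edge length, mm.
#' @return Area in mm^2.
#' @export
faz_area <- function(faz_mask, pixel_size_mm) {
  assert_scalar_positive(pixel_size_mm, "pixel_size_mm")
  comp <- largest_component(as_mask(faz_mask), "faz_area")
  sum(comp) * pixel_size_mm^2
}

# Ordered outer-boundary polygon of a single-component mask, as an
# n x 2 matrix of (row, col) in 1-based pixel coordinates.
trace_boundary <- function(mask) {
  oc <- EBImage::ocontour(mask * 1)
  if (!length(oc)) return(matrix(numeric(0), 0, 2))
  # EBImage returns 0-based (x, y) = (row-1, col-1) for matrix input
  oc[[1L]] + 1
}

#' FAZ perimeter
#'
#' Length of the traced outer-boundary polygon of the (largest) FAZ
#' component: the 8-connected boundary is walked in order and consecutive
#' boundary pixels contribute segments of length 1 (orthogonal step) or
#' sqrt(2) (diagonal step); the polygon is closed. A single-pixel region
#' has no closed contour and returns 0 with a warning.
#'
#' @param faz_mask Logical matrix.
#' @param pixel_size_mm Pixel edge length, mm.
#' @return Perimeter in mm.
#' @export
faz_perimeter <- function(faz_mask, pixel_size_mm) {
  assert_scalar_positive(pixel_size_mm, "pixel_size_mm")
  comp <- largest_component(as_mask(faz_mask), "faz_perimeter")
  if (sum(comp) == 1L) {
    warning("faz_perimeter: single-pixel region; perimeter defined as 0")
    return(0)
  }
  pts <- trace_boundary(comp)
  pts <- rbind(pts, pts[1L, ])
  sum(sqrt(rowSums(diff(pts)^2))) * pixel_size_mm
}

#' Vessel boundary pixels
#'
#' Foreground pixels whose 3x3 neighborhood contains at least one
#' background (or off-grid) pixel.
#'
#' @param vessel_mask Logical matrix.
#' @return Logical matrix, a subset of `vessel_mask`.
#' @export
vessel_boundary <- function(vessel_mask) {
  m <- as_mask(vessel_mask)
  interior <- m
  for (r in seq_len(nrow(offsets8)))
    interior <- interior & shift_mat(m, offsets8[r, 1], offsets8[r, 2],
                                     fill = FALSE)
  m & !interior
}

# Zhang-Suen morphological thinning to a 1-pixel-wide skeleton.
skeletonize <- function(mask) {
  m <- as_mask(mask) * 1L
  neigh <- function(m) {
    # P2..P9 clockwise from north, in (row, col) with row 1 at top
    list(p2 = shift_mat(m, -1, 0), p3 = shift_mat(m, -1, 1),
         p4 = shift_mat(m, 0, 1),  p5 = shift_mat(m, 1, 1),
         p6 = shift_mat(m, 1, 0),  p7 = shift_mat(m, 1, -1),
         p8 = shift_mat(m, 0, -1), p9 = shift_mat(m, -1, -1))
  }
  repeat {
    changed <- FALSE
    for (step in 1:2) {
      np <- neigh(m)
      B <- np$p2 + np$p3 + np$p4 + np$p5 + np$p6 + np$p7 + np$p8 + np$p9
      seqs <- list(np$p2, np$p3, np$p4, np$p5, np$p6, np$p7, np$p8, np$p9,
                   np$p2)
      A <- matrix(0L, nrow(m), ncol(m))
      for (i in 1:8) A <- A + (seqs[[i]] == 0L & seqs[[i + 1L]] == 1L)
      if (step == 1) {
        c1 <- np$p2 * np$p4 * np$p6 == 0L
        c2 <- np$p4 * np$p6 * np$p8 == 0L
      } else {
        c1 <- np$p2 * np$p4 * np$p8 == 0L
        c2 <- np$p2 * np$p6 * np$p8 == 0L
      }
      del <- m == 1L & B >= 2L & B <= 6L & A == 1L & c1 & c2
      if (any(del)) { m[del] <- 0L; changed <- TRUE }
    }
    if (!changed) break
  }
  m == 1L
}

# Crossing number of each skeleton pixel: the number of 0->1 transitions
# around its 8-neighborhood, i.e. the number of distinct branches leaving
# the pixel. 1 = endpoint, 2 = path interior (including staircase
# corners, which have 3 raw neighbors), >= 3 = junction.
skeleton_crossings <- function(sk) {
  m <- sk * 1L
  np <- list(shift_mat(m, -1, 0), shift_mat(m, -1, 1), shift_mat(m, 0, 1),
             shift_mat(m, 1, 1), shift_mat(m, 1, 0), shift_mat(m, 1, -1),
             shift_mat(m, 0, -1), shift_mat(m, -1, -1))
  np <- c(np, np[1])
  A <- matrix(0L, nrow(sk), ncol(sk))
  for (i in 1:8) A <- A + (np[[i]] == 0L & np[[i + 1L]] == 1L)
  A[!sk] <- 0L
  A
}

#' Extract ordered vessel centerline paths
#'
#' Thins the vessel mask to a 1-pixel skeleton (Zhang-Suen), removes
#' junction pixels (crossing number >= 3, i.e. more than 2 distinct
#' branches meet) together with their immediate neighborhood so branches
#' separate cleanly, and orders each remaining branch end-to-end. Closed
#' loops (no endpoints) are returned with attribute `closed = TRUE`.
#' Branches shorter than `min_path_len` pixels are dropped.
#'
#' @param vessel_mask Logical matrix (cleaned).
#' @param min_path_len Minimum retained path length in pixels (default 5).
#' @return List of n x 2 matrices of ordered (row, col) coordinates.
#' @export
extract_centerlines <- function(vessel_mask, min_path_len = 5) {
  sk <- skeletonize(vessel_mask)
  if (!any(sk)) return(list())
  cr <- skeleton_crossings(sk)
  # remove each junction with its 8-neighborhood: branch tips around a
  # junction are mutually diagonal, so removing the junction pixel alone
  # would leave the branches glued together
  junc <- sk & cr >= 3L
  cut <- junc
  for (r in seq_len(nrow(offsets8)))
    cut <- cut | shift_mat(junc, offsets8[r, 1], offsets8[r, 2], fill = FALSE)
  branches <- sk & !cut
  if (!any(branches)) return(list())
  lab <- label_components(branches)
  paths <- list()
  for (cid in seq_len(max(lab))) {
    pix <- which(lab == cid, arr.ind = TRUE)
    if (nrow(pix) < min_path_len) next
    paths[[length(paths) + 1L]] <- order_path(pix)
  }
  paths
}

# Order the pixels of a simple 8-connected path (or loop) end-to-end.
order_path <- function(pix) {
  n <- nrow(pix)
  key <- paste(pix[, 1], pix[, 2])
  index <- stats::setNames(seq_len(n), key)
  nbrs <- function(i) {
    cand <- cbind(pix[i, 1] + offsets8[, 1], pix[i, 2] + offsets8[, 2])
    hits <- index[paste(cand[, 1], cand[, 2])]
    hits[!is.na(hits)]
  }
  degs <- vapply(seq_len(n), function(i) length(nbrs(i)), 1L)
  start <- if (any(degs == 1L)) which(degs == 1L)[1L] else 1L
  closed <- !any(degs == 1L)
  visited <- rep(FALSE, n)
  ord <- integer(n)
  cur <- start
  for (step in seq_len(n)) {
    ord[step] <- cur
    visited[cur] <- TRUE
    nxt <- nbrs(cur)
    nxt <- nxt[!visited[nxt]]
    if (!length(nxt)) break
    if (length(nxt) > 1L) {
      # prefer orthogonal continuation over diagonal shortcuts
      dist <- abs(pix[nxt, 1] - pix[cur, 1]) + abs(pix[nxt, 2] - pix[cur, 2])
      nxt <- nxt[order(dist)]
    }
    cur <- nxt[1L]
  }
  ord <- ord[seq_len(step)]
  out <- pix[ord, , drop = FALSE]
  attr(out, "closed") <- closed
  out
}

# index-wise gradient: central differences, one-sided at the ends
# (circular differences when closed).
grad1 <- function(v, closed = FALSE) {
  n <- length(v)
  if (closed) {
    (c(v[-1], v[1]) - c(v[n], v[-n])) / 2
  } else {
    g <- numeric(n)
    g[1] <- v[2] - v[1]
    g[n] <- v[n] - v[n - 1]
    if (n > 2) g[2:(n - 1)] <- (v[3:n] - v[1:(n - 2)]) / 2
    g
  }
}

smooth_coords <- function(v, sigma, closed) {
  if (sigma <= 0) return(v)
  h <- ceiling(3 * sigma)
  k <- stats::dnorm(-h:h, sd = sigma)
  k <- k / sum(k)
  n <- length(v)
  if (closed) {
    idx <- function(i) ((i - 1) %% n) + 1
    vapply(seq_len(n), function(i) sum(k * v[idx((i - h):(i + h))]), 1)
  } else {
    # reflect at the ends (clamped for paths shorter than the kernel)
    idx <- function(i) {
      i <- ifelse(i < 1, 2 - i, i)
      i <- ifelse(i > n, 2 * n - i, i)
      pmin(pmax(i, 1), n)
    }
    vapply(seq_len(n), function(i) sum(k * v[idx((i - h):(i + h))]), 1)
  }
}

#' Per-point curvature along an ordered path
#'
#' First- and second-order index-wise gradients of the coordinates give
#' `kappa = |x' y'' - y' x''| / (x'^2 + y'^2)^(3/2)` (units 1/pixel).
#' Interior points use central differences; endpoints one-sided ones.
#' For integer (rasterized) coordinates the staircase dominates the second
#' differences, so a Gaussian smoothing of the coordinate functions along
#' the path (`smooth_sigma`, in pixels) should be applied first;
#' `smooth_sigma = 0` (default) differentiates the raw coordinates.
#'
#' @param path n x 2 matrix of ordered (row, col) coordinates, n >= 5;
#'   attribute `closed = TRUE` makes all differences circular.
#' @param smooth_sigma Gaussian smoothing SD along the arc, pixels.
#' @return Numeric vector of per-point curvature (1/pixel). Points with a
#'   vanishing first derivative get 0 with a warning.
#' @export
path_curvature <- function(path, smooth_sigma = 0) {
  path <- as.matrix(path)
  if (nrow(path) < 5L)
    stop("path_curvature: path must have at least 5 points", call. = FALSE)
  closed <- isTRUE(attr(path, "closed"))
  x <- smooth_coords(path[, 1], smooth_sigma, closed)
  y <- smooth_coords(path[, 2], smooth_sigma, closed)
  xp <- grad1(x, closed); yp <- grad1(y, closed)
  xpp <- grad1(xp, closed); ypp <- grad1(yp, closed)
  sp2 <- xp^2 + yp^2
  k <- numeric(length(xp))
  ok <- sp2 > 1e-12
  if (!all(ok))
    warning("path_curvature: zero first derivative at some points; curvature set to 0")
  k[ok] <- abs(xp[ok] * ypp[ok] - yp[ok] * xpp[ok]) / sp2[ok]^1.5
  attr(k, "speed2") <- sp2
  k
}

#' Retinal blood vessel curvature (RBVC)
#'
#' Mean per-point curvature pooled over all retained vessel centerline
#' paths — a tortuosity index. Reported both per pixel and per mm.
#'
#' @param vessel_mask Logical matrix (cleaned vessel segmentation).
#' @param pixel_size_mm Pixel edge length, mm.
#' @param min_path_len Minimum centerline length, pixels.
#' @param smooth_sigma Coordinate smoothing SD (pixels) before
#'   differentiation; default 3 (suited to integer-pixel centerlines).
#' @param aggregate `"mean"` (default), `"median"`, or
#'   `"length_weighted"` (identical to `"mean"` over the pooled points;
#'   kept as an explicit option since per-path means weight paths equally).
#' @return List with `rbvc_per_px`, `rbvc_per_mm`, `n_paths`, `n_points`.
#' @export
rbvc <- function(vessel_mask, pixel_size_mm, min_path_len = 5,
                 smooth_sigma = 3,
                 aggregate = c("mean", "median", "length_weighted")) {
  aggregate <- match.arg(aggregate)
  assert_scalar_positive(pixel_size_mm, "pixel_size_mm")
  paths <- extract_centerlines(vessel_mask, min_path_len)
  if (!length(paths))
    stop("rbvc: no centerline paths retained", call. = FALSE)
  # on open paths the smoothing window is truncated near the ends, which
  # inflates the second differences there; pool only points with full
  # kernel support (at least the central 5 points), and drop points whose
  # smoothed speed collapsed below 0.5 px/step (over-smoothed stubs: on a
  # unit-spaced centerline the arc speed is ~1, so a much smaller value
  # means the kernel had no support and the curvature ratio is degenerate)
  h <- ceiling(3 * smooth_sigma)
  ks <- lapply(paths, function(p) {
    k <- path_curvature(p, smooth_sigma = smooth_sigma)
    sp2 <- attr(k, "speed2")
    n <- length(k)
    if (!isTRUE(attr(p, "closed")) && h > 0) {
      trim <- min(h, floor((n - 5) / 2))
      if (trim > 0) {
        keep <- (trim + 1):(n - trim)
        k <- k[keep]; sp2 <- sp2[keep]
      }
    }
    k[sp2 >= 0.25]
  })
  pooled <- unlist(ks)
  if (!length(pooled))
    stop("rbvc: no well-supported centerline points retained", call. = FALSE)
  val <- switch(aggregate,
                mean = mean(pooled),
                median = stats::median(pooled),
                length_weighted = mean(pooled))
  list(rbvc_per_px = val, rbvc_per_mm = val / pixel_size_mm,
       n_paths = length(paths), n_points = length(pooled))
}

#' Mean layer thickness
#'
#' @param thickness_map Numeric matrix in micrometres.
#' @param region_mask Optional logical matrix; `NULL` averages the whole map.
#' @return Mean thickness in micrometres.
#' @export
layer_thickness_mean <- function(thickness_map, region_mask = NULL) {
  m <- as.matrix(thickness_map)
  if (is.null(region_mask)) region_mask <- matrix(TRUE, nrow(m), ncol(m))
  region_mask <- as_mask(region_mask)
  if (!any(region_mask))
    stop("layer_thickness_mean: empty region", call. = FALSE)
  vals <- m[region_mask]
  if (any(!is.finite(vals)))
    stop("layer_thickness_mean: non-finite thickness values in region",
         call. = FALSE)
  mean(vals)
}

#' All ophthalmic biometrics for one retinal image set
#'
#' @param img A [retinal_image_set()].
#' @param min_area_px Small-object cleanup threshold, pixels.
#' @param min_quality Quality gate threshold.
#' @param rbvc_smooth_sigma Centerline coordinate smoothing, pixels.
#' @return One-row data frame: `faz_area_mm2`, `faz_perimeter_mm`,
#'   `rbvc_per_px`, `rbvc_per_mm`, `rnfl_um`, `gcl_ipl_um`, `quality_pass`.
#' @export
retinal_biometrics <- function(img, min_area_px = 5, min_quality = 6,
                               rbvc_smooth_sigma = 3) {
  stopifnot(inherits(img, "retinal_image_set"))
  faz <- clean_components(img$faz_mask, min_area_px)
  ves <- clean_components(img$vessel_mask, min_area_px)
  rb <- rbvc(ves, img$pixel_size_mm, smooth_sigma = rbvc_smooth_sigma)
  data.frame(
    faz_area_mm2 = faz_area(faz, img$pixel_size_mm),
    faz_perimeter_mm = faz_perimeter(faz, img$pixel_size_mm),
    rbvc_per_px = rb$rbvc_per_px,
    rbvc_per_mm = rb$rbvc_per_mm,
    rnfl_um = if ("RNFL" %in% names(img$thickness_maps))
      layer_thickness_mean(img$thickness_maps$RNFL) else NA_real_,
    gcl_ipl_um = if ("GCL_IPL" %in% names(img$thickness_maps))
      layer_thickness_mean(img$thickness_maps$GCL_IPL) else NA_real_,
    quality_pass = quality_gate(img, min_quality)
  )
}
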