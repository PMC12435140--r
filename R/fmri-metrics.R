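# Resting-state fMRI metrics: the processing chain is
#   discard initial volumes -> linear detrend -> nuisance regression
#   (Friston-24 motion expansion + global/WM/CSF means) -> FALFF and
#   (on band-pass-filtered residuals) ReHo -> standardization by the
#   in-mask mean -> optional Gaussian smoothing.
# FALFF is the fraction of sqrt-power in the 0.01-0.1 Hz band; ReHo is
# Kendall's coefficient of concordance (W) of each voxel with its 26
# neighbors.

#' Discard initial volumes of a 4D series
#'
#' Dummy scans at the start of a resting-state run are dropped before any
#' analysis (e.g., 185 acquired volumes minus 10 discarded leaves 175).
#'
#' @param vol A [voxel_volume()].
#' @param n_discard Number of leading volumes to drop (< number of volumes).
#' @return A [voxel_volume()] with the remaining frames, unchanged.
#' @export
discard_initial_volumes <- function(vol, n_discard = 10) {
  stopifnot(inherits(vol, "voxel_volume"))
  nt <- dim(vol$data)[4L]
  if (n_discard < 0 || n_discard != round(n_discard))
    stop("discard_initial_volumes: n_discard must be a non-negative integer",
         call. = FALSE)
  if (n_discard >= nt)
    stop(sprintf(
      "discard_initial_volumes: n_discard (%d) must be < number of volumes (%d)",
      n_discard, nt), call. = FALSE)
  if (n_discard == 0) return(vol)
  voxel_volume(vol$data[, , , (n_discard + 1L):nt, drop = FALSE],
               vol$affine, vol$tr)
}

#' Remove the linear trend from time series
#'
#' Least-squares removal of intercept and slope against the time index.
#' Accepts a vector or a matrix with one series per column.
#'
#' @param ts Numeric vector (length >= 3) or matrix (rows = time points).
#' @return Residual series, same shape; zero mean and zero covariance with
#'   the time index.
#' @export
detrend_linear <- function(ts) {
  x <- as.matrix(ts)
  n <- nrow(x)
  if (n < 3L)
    stop("detrend_linear: need at least 3 time points", call. = FALSE)
  X <- cbind(1, seq_len(n))
  res <- stats::lm.fit(X, x)$residuals
  if (is.vector(ts)) as.vector(res) else res
}

#' Friston-24 motion parameter expansion
#'
#' Expands a t x 6 rigid-body motion table to the 24-regressor set
#' `[R, R^2, R_lag1, R_lag1^2]`, where the lagged blocks are the
#' parameters at the previous time point, with the first row set to zero.
#'
#' @param motion Numeric matrix with 6 columns (3 translations, 3 rotations)
#'   and one row per retained volume.
#' @return t x 24 matrix with descriptive column names.
#' @export
expand_friston24 <- function(motion) {
  motion <- as.matrix(motion)
  if (ncol(motion) != 6L)
    stop("expand_friston24: motion table must have exactly 6 columns",
         call. = FALSE)
  nt <- nrow(motion)
  lag1 <- rbind(rep(0, 6L), motion[-nt, , drop = FALSE])
  out <- cbind(motion, motion^2, lag1, lag1^2)
  colnames(out) <- c(paste0("mp", 1:6), paste0("mp", 1:6, "_sq"),
                     paste0("mp", 1:6, "_lag"), paste0("mp", 1:6, "_lagsq"))
  out
}

#' Assemble a nuisance design matrix
#'
#' Intercept, Friston-24 motion expansion, and mean global / white-matter /
#' CSF signals (those supplied). Duplicate constant columns are dropped;
#' a rank-deficient design is an error naming the collinear columns.
#'
#' @param motion24 t x 24 matrix from [expand_friston24()].
#' @param global,wm,csf Optional length-t mean signals.
#' @return t x k design matrix with an `"intercept"` column.
#' @export
nuisance_design <- function(motion24, global = NULL, wm = NULL, csf = NULL) {
  motion24 <- as.matrix(motion24)
  nt <- nrow(motion24)
  X <- cbind(intercept = rep(1, nt), motion24)
  for (nm in c("global", "wm", "csf")) {
    v <- get(nm)
    if (!is.null(v)) {
      if (length(v) != nt)
        stop(sprintf("nuisance_design: '%s' has length %d, expected %d",
                     nm, length(v), nt), call. = FALSE)
      X <- cbind(X, v)
      colnames(X)[ncol(X)] <- nm
    }
  }
  # drop constant duplicates of the intercept (e.g., all-zero motion cols)
  keep <- c(TRUE, apply(X[, -1L, drop = FALSE], 2L,
                        function(col) stats::sd(col) > 0))
  X <- X[, keep, drop = FALSE]
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop("nuisance_design: collinear columns: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  X
}

#' Regress nuisance signals out of time series
#'
#' Returns the least-squares residual of each series against the design;
#' residuals are orthogonal to every design column.
#'
#' @param ts Numeric vector or matrix (rows = time points).
#' @param design t x k design matrix (must include the intercept if mean
#'   removal is wanted).
#' @return Residual series, same shape as `ts`.
#' @export
regress_nuisance <- function(ts, design) {
  x <- as.matrix(ts)
  design <- as.matrix(design)
  if (nrow(design) != nrow(x))
    stop(sprintf("regress_nuisance: design has %d rows, series has %d",
                 nrow(design), nrow(x)), call. = FALSE)
  qrX <- qr(design)
  if (qrX$rank < ncol(design)) {
    nm <- colnames(design)
    if (is.null(nm)) nm <- paste0("col", seq_len(ncol(design)))
    bad <- nm[qrX$pivot[(qrX$rank + 1L):ncol(design)]]
    stop("regress_nuisance: rank-deficient design; collinear columns: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  res <- qr.resid(qrX, x)
  if (is.vector(ts)) as.vector(res) else res
}

# Direct-form IIR filter applied to every column of X (vectorized over
# columns; the time recursion is the only loop).
iir_filter_cols <- function(b, a, X) {
  b <- b / a[1]; a <- a / a[1]
  nb <- length(b); na <- length(a)
  nt <- nrow(X); nc <- ncol(X)
  Y <- matrix(0, nt, nc)
  for (t in seq_len(nt)) {
    acc <- b[1] * X[t, ]
    if (t >= 2L) {
      for (i in 2:min(nb, t))
        acc <- acc + b[i] * X[t - i + 1L, ]
      for (j in 2:min(na, t))
        acc <- acc - a[j] * Y[t - j + 1L, ]
    }
    Y[t, ] <- acc
  }
  Y
}

#' Zero-phase band-pass filter
#'
#' 4th-order Butterworth band-pass applied forward and backward (zero
#' phase), with odd-reflection edge padding. Used before ReHo so
#' concordance is computed on the 0.01-0.1 Hz band. Vectorized over the
#' columns of a matrix input.
#'
#' @param ts Numeric vector or matrix (rows = time points).
#' @param tr Repetition time, seconds.
#' @param band `c(f_lo, f_hi)` in Hz, within (0, Nyquist).
#' @param order Butterworth order.
#' @return Filtered series, same shape.
#' @export
bandpass_filter <- function(ts, tr, band = c(0.01, 0.1), order = 4) {
  assert_scalar_positive(tr, "tr")
  nyq <- 1 / (2 * tr)
  if (band[1] <= 0 || band[2] >= nyq || band[1] >= band[2])
    stop("bandpass_filter: band must satisfy 0 < f_lo < f_hi < Nyquist",
         call. = FALSE)
  bf <- signal::butter(order, band / nyq, type = "pass")
  b <- as.numeric(bf$b); a <- as.numeric(bf$a)
  x <- as.matrix(ts)
  nt <- nrow(x)
  npad <- min(3L * (length(a) - 1L) * 3L, nt - 1L)
  top <- 2 * matrix(x[1, ], npad, ncol(x), byrow = TRUE) -
    x[(npad + 1L):2, , drop = FALSE]
  bot <- 2 * matrix(x[nt, ], npad, ncol(x), byrow = TRUE) -
    x[(nt - 1L):(nt - npad), , drop = FALSE]
  xp <- rbind(top, x, bot)
  y <- iir_filter_cols(b, a, xp)
  y <- iir_filter_cols(b, a, y[nrow(y):1, , drop = FALSE])
  y <- y[nrow(y):1, , drop = FALSE]
  out <- y[(npad + 1L):(npad + nt), , drop = FALSE]
  if (is.vector(ts)) as.vector(out) else out
}

# positive-frequency DFT bin frequencies for a length-n series
dft_freqs <- function(n, tr) {
  kmax <- floor(n / 2)
  (seq_len(kmax)) / (n * tr)
}

#' Fractional amplitude of low-frequency fluctuations (FALFF)
#'
#' Ratio of summed square-root power (DFT amplitude) over the frequency
#' band to that over all positive-frequency bins. The DC bin is excluded
#' (it carries only the series mean); a bin is in-band when
#' `f_lo <= f <= f_hi` on the DFT frequency grid. Result is in `[0, 1]`
#' and invariant under rescaling of the series.
#'
#' @param ts Numeric vector, length >= 8.
#' @param tr Repetition time, seconds.
#' @param band `c(f_lo, f_hi)` in Hz, `0 < f_lo < f_hi <= Nyquist`.
#' @return Scalar in `[0, 1]`; 0 with a warning for a constant series.
#' @export
compute_falff <- function(ts, tr, band = c(0.01, 0.1)) {
  n <- length(ts)
  if (n < 8L) stop("compute_falff: need at least 8 time points", call. = FALSE)
  assert_scalar_positive(tr, "tr")
  nyq <- 1 / (2 * tr)
  if (band[1] <= 0 || band[2] > nyq || band[1] >= band[2])
    stop("compute_falff: band must satisfy 0 < f_lo < f_hi <= Nyquist",
         call. = FALSE)
  if (stats::sd(ts) == 0) {
    warning("compute_falff: constant series; FALFF defined as 0")
    return(0)
  }
  amp <- Mod(stats::fft(ts))[2:(floor(n / 2) + 1L)]
  f <- dft_freqs(n, tr)
  sum(amp[f >= band[1] & f <= band[2]]) / sum(amp)
}

# Vectorized FALFF over the columns of a t x V matrix.
falff_matrix <- function(mat, tr, band = c(0.01, 0.1)) {
  n <- nrow(mat)
  const <- apply(mat, 2L, stats::sd) == 0
  amp <- Mod(stats::mvfft(mat))[2:(floor(n / 2) + 1L), , drop = FALSE]
  f <- dft_freqs(n, tr)
  tot <- colSums(amp)
  out <- ifelse(!const & tot > 0,
                colSums(amp[f >= band[1] & f <= band[2], ,
                            drop = FALSE]) / tot, 0)
  if (any(const))
    warning("falff_matrix: constant series; FALFF defined as 0")
  out
}

#' FALFF map of a 4D volume
#'
#' @param vol A [voxel_volume()] (already detrended / nuisance-regressed).
#' @param mask 3D logical array of voxels to evaluate.
#' @param band Frequency band in Hz.
#' @return A [metric_map()] named `"FALFF"`; out-of-mask voxels are 0.
#' @export
compute_falff_map <- function(vol, mask, band = c(0.01, 0.1)) {
  stopifnot(inherits(vol, "voxel_volume"))
  mask <- check_mask(mask, dim(vol$data)[1:3])
  d <- dim(vol$data)
  mat <- matrix(aperm(vol$data, c(4, 1, 2, 3)), nrow = d[4])[, as.vector(mask),
                                                             drop = FALSE]
  vals <- falff_matrix(mat, vol$tr, band)
  out <- array(0, d[1:3])
  out[mask] <- vals
  metric_map(out, vol$affine, "FALFF")
}

#' Kendall's coefficient of concordance (KCC)
#'
#' Concordance W of k time series over n time points, with the standard
#' tie correction: ranks are taken over time within each series,
#' `S = sum_i (R_i - mean(R))^2` over time-point rank sums, and
#' `W = 12 S / (k^2 (n^3 - n) - k sum_j T_j)` with
#' `T_j = sum over tie groups (t^3 - t)`. W lies in `[0, 1]` and is
#' invariant under strictly monotone transforms of each series.
#'
#' @param series Numeric matrix, one series per column (n rows = time
#'   points, k >= 2 columns).
#' @return W in `[0, 1]`; 0 with a warning if the tie-corrected
#'   denominator vanishes (e.g., all series constant).
#' @export
compute_kcc <- function(series) {
  m <- as.matrix(series)
  n <- nrow(m); k <- ncol(m)
  if (k < 2L || n < 2L)
    stop("compute_kcc: need k >= 2 series and n >= 2 time points",
         call. = FALSE)
  ranks <- apply(m, 2L, rank)
  Ri <- rowSums(ranks)
  S <- sum((Ri - mean(Ri))^2)
  Tj <- apply(m, 2L, function(col) {
    tt <- table(col)
    sum(tt^3 - tt)
  })
  denom <- k^2 * (n^3 - n) - k * sum(Tj)
  if (denom <= 0) {
    warning("compute_kcc: degenerate (all-tied) series; W defined as 0")
    return(0)
  }
  12 * S / denom
}

# Sparse V x V neighbor-incidence matrix (self + in-mask 26-neighbors)
# for the in-mask voxels of a 3D logical mask.
neighbor_matrix_26 <- function(mask) {
  d <- dim(mask)
  idx <- which(mask)
  coord <- arrayInd(idx, d)
  vox_id <- array(0L, d)
  vox_id[idx] <- seq_along(idx)
  from <- integer(0); to <- integer(0)
  for (di in -1:1) for (dj in -1:1) for (dk in -1:1) {
    ni <- coord[, 1] + di; nj <- coord[, 2] + dj; nk <- coord[, 3] + dk
    ok <- ni >= 1 & ni <= d[1] & nj >= 1 & nj <= d[2] & nk >= 1 & nk <= d[3]
    nb <- rep(0L, nrow(coord))
    nb[ok] <- vox_id[cbind(ni[ok], nj[ok], nk[ok])]
    hit <- nb > 0L
    from <- c(from, which(hit))
    to <- c(to, nb[hit])
  }
  Matrix::sparseMatrix(i = to, j = from, x = 1,
                       dims = c(length(idx), length(idx)))
}

#' Regional homogeneity (ReHo) map
#'
#' Per in-mask voxel, the Kendall concordance W of the voxel's series with
#' its in-mask subset of the 26 face/edge/corner neighbors. Neighborhoods
#' with fewer than 2 in-mask members get 0 (with a warning).
#'
#' @param vol A [voxel_volume()] (typically band-pass-filtered residuals).
#' @param mask 3D logical array.
#' @return A [metric_map()] named `"ReHo"`.
#' @export
compute_reho_map <- function(vol, mask) {
  stopifnot(inherits(vol, "voxel_volume"))
  d <- dim(vol$data)
  mask <- check_mask(mask, d[1:3])
  nt <- d[4]
  idx <- which(mask)
  mat <- matrix(aperm(vol$data, c(4, 1, 2, 3)), nrow = nt)[, idx,
                                                           drop = FALSE]
  ranks <- apply(mat, 2L, rank)                       # nt x V
  Tj <- apply(mat, 2L, function(col) {
    if (!anyDuplicated(col)) return(0)                # continuous: no ties
    tt <- table(col)
    sum(tt^3 - tt)
  })
  N <- neighbor_matrix_26(mask)                       # V x V
  k <- as.vector(Matrix::colSums(N))
  Rsum <- as.matrix(ranks %*% N)                      # nt x V rank sums
  S <- colSums(sweep(Rsum, 2L, k * (nt + 1) / 2)^2)
  Tsum <- as.vector(Tj %*% N)
  denom <- k^2 * (nt^3 - nt) - k * Tsum
  W <- ifelse(k >= 2 & denom > 0, 12 * S / pmax(denom, 1e-300), 0)
  if (any(k < 2))
    warning("compute_reho_map: voxels with < 2 in-mask neighborhood members set to 0")
  out <- array(0, d[1:3])
  out[idx] <- W
  metric_map(out, vol$affine, "ReHo")
}

#' Standardize a metric map by its in-mask mean
#'
#' Divides the map by the mean over the brain mask, so the in-mask mean of
#' the result is exactly 1. Idempotent.
#'
#' @param map A [metric_map()].
#' @param mask 3D logical array; its mean of `map` must be nonzero.
#' @return Standardized [metric_map()].
#' @export
standardize_map <- function(map, mask) {
  stopifnot(inherits(map, "metric_map"))
  mask <- check_mask(mask, dim(map$data))
  mu <- mean(map$data[mask])
  if (!is.finite(mu) || mu == 0)
    stop("standardize_map: in-mask mean is zero or non-finite", call. = FALSE)
  metric_map(map$data / mu, map$affine, map$metric, standardized = TRUE)
}

# 1D zero-padded convolution of every row of a matrix with kernel k.
conv_rows <- function(m, k) {
  h <- (length(k) - 1L) / 2L
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0, nr, nc)
  for (tap in seq_along(k)) {
    off <- tap - 1L - h
    src <- seq_len(nc) + off
    ok <- src >= 1L & src <= nc
    out[, which(ok)] <- out[, which(ok)] + k[tap] * m[, src[ok], drop = FALSE]
  }
  out
}

#' Separable Gaussian smoothing of a 3D map
#'
#' Convolution with a separable Gaussian of full width at half maximum
#' `fwhm_mm`; per axis, `sigma = fwhm / (2 sqrt(2 ln 2)) / voxel_size`
#' in voxel units. The kernel is truncated at 4 sigma and normalized to
#' sum 1; the volume is zero-padded at the edges. `fwhm_mm = 0` is the
#' identity.
#'
#' @param map A [metric_map()].
#' @param fwhm_mm FWHM in millimetres (>= 0).
#' @param voxel_size_mm Voxel edge lengths in mm (scalar or length 3).
#' @return Smoothed [metric_map()].
#' @export
gaussian_smooth <- function(map, fwhm_mm, voxel_size_mm = 3) {
  stopifnot(inherits(map, "metric_map"))
  if (fwhm_mm < 0)
    stop("gaussian_smooth: fwhm_mm must be >= 0", call. = FALSE)
  if (fwhm_mm == 0) return(map)
  vs <- rep_len(voxel_size_mm, 3L)
  x <- map$data
  d <- dim(x)
  for (ax in 1:3) {
    sigma <- fwhm_mm / (2 * sqrt(2 * log(2))) / vs[ax]
    r <- max(1L, ceiling(4 * sigma))
    k <- stats::dnorm(-r:r, sd = sigma)
    k <- k / sum(k)
    perm <- switch(ax, c(2, 3, 1), c(1, 3, 2), c(1, 2, 3))
    inv <- order(perm)
    xp <- aperm(x, perm)
    dp <- dim(xp)
    m <- matrix(xp, nrow = dp[1] * dp[2], ncol = dp[3])
    m <- conv_rows(m, k)
    x <- aperm(array(m, dp), inv)
  }
  metric_map(x, map$affine, map$metric, map$standardized)
}

#' Group gray-matter mask
#'
#' Thresholds the voxel-wise mean of the subjects' gray-matter probability
#' maps: a voxel is in the mask when the mean probability is `>= threshold`
#' (default 0.2).
#'
#' @param prob_maps List of 3D arrays on a common grid, values in `[0, 1]`.
#' @param threshold Scalar in `[0, 1]`.
#' @return 3D logical array.
#' @export
build_group_gm_mask <- function(prob_maps, threshold = 0.2) {
  if (!length(prob_maps))
    stop("build_group_gm_mask: empty list of probability maps", call. = FALSE)
  if (threshold < 0 || threshold > 1)
    stop("build_group_gm_mask: threshold must be in [0, 1]", call. = FALSE)
  d <- dim(prob_maps[[1L]])
  for (m in prob_maps)
    if (!identical(dim(m), d))
      stop("build_group_gm_mask: probability maps are not on a common grid",
           call. = FALSE)
  acc <- Reduce(`+`, prob_maps) / length(prob_maps)
  acc >= threshold
}

check_mask <- function(mask, d) {
  mask <- array(as.logical(mask), dim = dim(mask))
  if (!identical(dim(mask), as.integer(d)))
    stop("mask dimensions do not match the volume grid", call. = FALSE)
  if (!any(mask)) stop("mask is empty", call. = FALSE)
  mask
}

#' Full single-subject fMRI metric chain
#'
#' Runs discard -> detrend -> nuisance regression (Friston-24 + global
#' mean) -> FALFF, and ReHo on band-pass-filtered residuals, then
#' standardizes both maps by their in-mask mean. Smoothing is exposed but
#' off by default for functional maps.
#'
#' @param vol A [voxel_volume()] (raw series).
#' @param motion t x 6 motion-parameter table (rows = acquired volumes).
#' @param brain_mask 3D logical array (e.g., subject GM probability >= 0.5).
#' @param n_discard Leading volumes to drop (default 10).
#' @param band Frequency band in Hz (default 0.01-0.1).
#' @param fwhm_mm Smoothing FWHM in mm (default 0 = none).
#' @param voxel_size_mm Voxel size for smoothing.
#' @param wm,csf Optional nuisance mean signals (length = retained volumes).
#' @param channels Which metric maps to compute (`"falff"`, `"reho"`).
#' @return List with standardized `falff` and/or `reho` [metric_map()]s.
#' @export
process_fmri_subject <- function(vol, motion, brain_mask, n_discard = 10,
                                 band = c(0.01, 0.1), fwhm_mm = 0,
                                 voxel_size_mm = 3, wm = NULL, csf = NULL,
                                 channels = c("falff", "reho")) {
  channels <- match.arg(channels, several.ok = TRUE)
  stopifnot(inherits(vol, "voxel_volume"))
  motion <- as.matrix(motion)
  if (nrow(motion) != dim(vol$data)[4L])
    stop("process_fmri_subject: motion rows must equal acquired volumes",
         call. = FALSE)
  mask <- check_mask(brain_mask, dim(vol$data)[1:3])
  vol <- discard_initial_volumes(vol, n_discard)
  keep <- (n_discard + 1L):nrow(motion)
  d <- dim(vol$data)
  mat <- matrix(aperm(vol$data, c(4, 1, 2, 3)), nrow = d[4])
  mat <- detrend_linear(mat)
  global <- rowMeans(mat[, as.vector(mask), drop = FALSE])
  design <- nuisance_design(expand_friston24(motion[keep, , drop = FALSE]),
                            global = global, wm = wm, csf = csf)
  mat <- regress_nuisance(mat, design)
  out <- list()
  if ("falff" %in% channels) {
    resid_arr <- aperm(array(mat, c(d[4], d[1], d[2], d[3])), c(2, 3, 4, 1))
    resid_vol <- voxel_volume(resid_arr, vol$affine, vol$tr)
    falff <- standardize_map(compute_falff_map(resid_vol, mask, band), mask)
    if (fwhm_mm > 0) falff <- gaussian_smooth(falff, fwhm_mm, voxel_size_mm)
    out$falff <- falff
  }
  if ("reho" %in% channels) {
    mv <- as.vector(mask)
    filt <- matrix(0, d[4], prod(d[1:3]))
    filt[, mv] <- bandpass_filter(mat[, mv, drop = FALSE], vol$tr, band)
    filt_arr <- aperm(array(filt, c(d[4], d[1], d[2], d[3])), c(2, 3, 4, 1))
    reho <- compute_reho_map(voxel_volume(filt_arr, vol$affine, vol$tr), mask)
    reho <- standardize_map(reho, mask)
    if (fwhm_mm > 0) reho <- gaussian_smooth(reho, fwhm_mm, voxel_size_mm)
    out$reho <- reho
  }
  out
}
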