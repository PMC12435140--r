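# Independent oracles and small geometry builders used across tests.
# These deliberately use different formulations than the package code.

# Kendall's W via the alternative algebraic form
# W = (12 * sum(Ri^2) - 3 k^2 n (n+1)^2) / (k^2 n (n^2 - 1) - k * sumT)
oracle_kcc <- function(series) {
  m <- as.matrix(series)
  n <- nrow(m); k <- ncol(m)
  R <- apply(m, 2, function(col) rank(col, ties.method = "average"))
  Ri <- rowSums(R)
  sumT <- sum(apply(m, 2, function(col) {
    tt <- as.vector(table(col))
    sum(tt^3 - tt)
  }))
  num <- 12 * sum(Ri^2) - 3 * k^2 * n * (n + 1)^2
  den <- k^2 * n * (n^2 - 1) - k * sumT
  if (den <= 0) return(0)
  num / den
}

# OLS by explicit normal equations
oracle_ols <- function(y, X) {
  XtX <- t(X) %*% X
  beta <- solve(XtX, t(X) %*% y)
  res <- y - X %*% beta
  df <- length(y) - ncol(X)
  se <- sqrt(diag(solve(XtX)) * sum(res^2) / df)
  list(beta = as.vector(beta), se = as.vector(se), df = df)
}

# dense (triple-loop) 3D Gaussian convolution with zero padding
oracle_conv3d <- function(x, fwhm_mm, voxel_mm) {
  sigma <- fwhm_mm / (2 * sqrt(2 * log(2))) / voxel_mm
  r <- max(1L, ceiling(4 * sigma))
  k1 <- dnorm(-r:r, sd = sigma); k1 <- k1 / sum(k1)
  K <- outer(outer(k1, k1), k1)  # (2r+1)^3 separable kernel
  d <- dim(x)
  out <- array(0, d)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (l in seq_len(d[3])) {
    acc <- 0
    for (a in -r:r) for (b in -r:r) for (cc in -r:r) {
      ii <- i + a; jj <- j + b; ll <- l + cc
      if (ii >= 1 && ii <= d[1] && jj >= 1 && jj <= d[2] &&
          ll >= 1 && ll <= d[3])
        acc <- acc + K[a + r + 1, b + r + 1, cc + r + 1] * x[ii, jj, ll]
    }
    out[i, j, l] <- acc
  }
  out
}

disc_mask <- function(size, center, radius) {
  g <- expand.grid(r = seq_len(size), c = seq_len(size))
  matrix((g$r - center[1])^2 + (g$c - center[2])^2 <= radius^2, size, size)
}

# rasterized circle ring of thickness ~3 px (for curvature tests)
ring_mask <- function(size, center, radius) {
  th <- seq(0, 2 * pi, length.out = 6000)
  pts <- unique(round(cbind(center[1] + radius * cos(th),
                            center[2] + radius * sin(th))))
  m <- matrix(FALSE, size, size)
  m[pts] <- TRUE
  for (di in -1:1) for (dj in -1:1)
    m <- m | cebconn:::shift_mat(m, di, dj, fill = FALSE)
  m
}

# straight radial vessels at multiples of 45 degrees (exactly straight
# rasterizations) on a square canvas
straight_vessel_mask <- function(size = 96, r0 = 18, r1 = 44) {
  ctr <- c(size / 2, size / 2)
  m <- matrix(FALSE, size, size)
  for (k in 0:7) {
    th <- k * pi / 4
    s <- seq(r0, r1, by = 0.5)
    pts <- unique(round(cbind(ctr[1] + s * cos(th), ctr[2] + s * sin(th))))
    for (di in -1:1) for (dj in -1:1)
      m[pmin(pmax(pts[, 1] + di, 1), size) +
          (pmin(pmax(pts[, 2] + dj, 1), size) - 1) * size] <- TRUE
  }
  m
}

# blob column indices of the planted effect within the in-mask matrix
blob_columns <- function(config, voxel_idx) {
  which(voxel_idx %in% which(planted_blob_mask(config)))
}
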