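# FALFF / ReHo processing chain.

make_vol <- function(data, tr = 2) voxel_volume(data, diag(4), tr)

test_that("discard_initial_volumes drops exactly the leading frames", {
  set.seed(21)
  a <- array(rnorm(3 * 3 * 2 * 185), c(3, 3, 2, 185))
  v <- make_vol(a)
  out <- discard_initial_volumes(v, 10)
  expect_equal(dim(out$data)[4], 175)
  expect_identical(out$data, a[, , , 11:185])
  expect_identical(discard_initial_volumes(v, 0)$data, a)
  small <- make_vol(a[, , , 1:12])
  out2 <- discard_initial_volumes(small, 10)
  expect_identical(out2$data, a[, , , 11:12])
  expect_error(discard_initial_volumes(small, 12), "must be <")
})

test_that("detrend_linear removes exactly the least-squares line", {
  n <- 50
  t_idx <- seq_len(n)
  expect_equal(detrend_linear(3 + 0.7 * t_idx), rep(0, n), tolerance = 1e-10)
  expect_equal(detrend_linear(rep(4.2, n)), rep(0, n), tolerance = 1e-12)
  set.seed(22)
  y <- 2 - 0.3 * t_idx + sin(t_idx / 3)
  res <- detrend_linear(y)
  X <- cbind(1, t_idx)
  oracle <- y - X %*% solve(t(X) %*% X, t(X) %*% y)
  expect_equal(res, as.vector(oracle), tolerance = 1e-10)
  expect_lt(abs(mean(res)), 1e-10)
  expect_lt(abs(sum(res * scale(t_idx, scale = FALSE))), 1e-8)
  expect_error(detrend_linear(c(1, 2)), "at least 3")
})

test_that("Friston-24 expansion has the documented layout", {
  z <- expand_friston24(matrix(0, 20, 6))
  expect_equal(dim(z), c(20, 24))
  expect_true(all(z == 0))
  m <- matrix(0, 10, 6); m[3, 2] <- 0.5
  e <- expand_friston24(m)
  nz <- which(e != 0, arr.ind = TRUE)
  # R at (3,2), R^2 at (3,8), lag at (4,14), lag^2 at (4,20)
  expect_equal(nrow(nz), 4)
  expect_setequal(paste(nz[, 1], nz[, 2]), c("3 2", "3 8", "4 14", "4 20"))
  expect_equal(unname(e[3, 8]), 0.25)
  set.seed(23)
  r <- matrix(rnorm(60), 10, 6)
  expect_true(all(expand_friston24(r)[1, 13:24] == 0))
  expect_error(expand_friston24(matrix(0, 5, 5)), "6 columns")
})

test_that("regress_nuisance projects out the design exactly", {
  set.seed(24)
  n <- 40
  X <- cbind(intercept = 1, a = rnorm(n), b = rnorm(n))
  expect_equal(regress_nuisance(X[, "a"], X), rep(0, n), tolerance = 1e-10)
  # a series orthogonal to all columns passes through unchanged
  y <- qr.resid(qr(X), rnorm(n))
  expect_equal(regress_nuisance(y, X), y, tolerance = 1e-10)
  y2 <- rnorm(n)
  oracle <- y2 - X %*% solve(t(X) %*% X, t(X) %*% y2)
  expect_equal(regress_nuisance(y2, X), as.vector(oracle), tolerance = 1e-8)
  res <- regress_nuisance(y2, X)
  expect_lt(max(abs(t(X) %*% res)) / sqrt(sum(y2^2)), 1e-8)
  Xbad <- cbind(X, dup = X[, "a"])
  expect_error(regress_nuisance(y2, Xbad), "dup")
})

test_that("FALFF is the banded fraction of DFT amplitude", {
  n <- 160; tr <- 2
  t_s <- seq_len(n) * tr
  # exactly on an in-band DFT bin: f = 16/(160*2) = 0.05 Hz
  expect_equal(compute_falff(sin(2 * pi * 0.05 * t_s + 0.3), tr), 1,
               tolerance = 1e-9)
  # exactly on an out-of-band bin: f = 64/320 = 0.2 Hz
  expect_equal(compute_falff(sin(2 * pi * 0.2 * t_s), tr), 0,
               tolerance = 1e-9)
  # white noise: E[FALFF] ~ sum over band bins of E|amp| / total
  set.seed(25)
  n2 <- 175
  f <- (1:floor(n2 / 2)) / (n2 * tr)
  expected <- mean(f >= 0.01 & f <= 0.1)
  mc <- mean(replicate(3000, compute_falff(rnorm(n2), tr)))
  expect_equal(mc, expected, tolerance = 0.02 / expected)
  # range and scale invariance
  x <- rnorm(100)
  v <- compute_falff(x, tr)
  expect_true(v >= 0 && v <= 1)
  expect_equal(compute_falff(7.3 * x, tr), v, tolerance = 1e-12)
  expect_error(compute_falff(rnorm(100), tr, band = c(0.2, 0.3)), "Nyquist")
  expect_warning(z <- compute_falff(rep(1, 100), tr), "constant")
  expect_equal(z, 0)
})

test_that("KCC matches the brute-force rank oracle and is monotone-invariant", {
  # perfect concordance
  m <- matrix(rep(c(0.3, 1.1, 2.5, 7, 9), 4), ncol = 4)
  expect_equal(compute_kcc(m), 1)
  # hand-enumerable k=3, n=3 instance (with a tie)
  m3 <- cbind(c(1, 2, 3), c(2, 1, 3), c(1, 1, 2))
  expect_equal(compute_kcc(m3), oracle_kcc(m3), tolerance = 1e-12)
  # random small instances, exact agreement
  set.seed(26)
  for (i in 1:25) {
    k <- sample(2:5, 1); n <- sample(3:6, 1)
    m <- matrix(sample(1:4, k * n, replace = TRUE) + rnorm(k * n, 0, 0.01),
                n, k)
    expect_equal(compute_kcc(m), oracle_kcc(m), tolerance = 1e-12)
  }
  # monotone per-series transform invariance
  set.seed(27)
  m <- matrix(rnorm(40), 10, 4)
  expect_equal(compute_kcc(m), compute_kcc(exp(m)), tolerance = 1e-12)
  # independence: E[W] = 1/k
  set.seed(28)
  k <- 5
  ws <- replicate(400, compute_kcc(matrix(rnorm(20 * k), 20, k)))
  expect_equal(mean(ws), 1 / k, tolerance = 0.1)
  expect_warning(w0 <- compute_kcc(matrix(1, 5, 3)), "degenerate")
  expect_equal(w0, 0)
})

test_that("ReHo map gives perfect concordance for shared monotone series", {
  d <- c(5, 5, 4); nt <- 12
  base <- sort(rnorm(nt))
  a <- array(rep(base, each = prod(d)), c(d, nt))
  mask <- array(TRUE, d)
  rh <- compute_reho_map(make_vol(a), mask)
  expect_true(all(abs(rh$data - 1) < 1e-12))
  # independent noise: small interior values, matching the KCC null scale
  set.seed(29)
  a2 <- array(rnorm(prod(d) * 40), c(d, 40))
  rh2 <- compute_reho_map(make_vol(a2), mask)
  interior <- rh2$data[2:4, 2:4, 2:3]
  expect_lt(mean(interior), 0.15)   # E[W] ~ 1/27 for 27 independent series
  expect_true(all(rh2$data >= 0 & rh2$data <= 1))
  # single-voxel mask degenerates to 0 with a warning
  m1 <- array(FALSE, d); m1[2, 2, 2] <- TRUE
  expect_warning(rh3 <- compute_reho_map(make_vol(a2), m1), "< 2")
  expect_equal(max(rh3$data), 0)
})

test_that("standardize_map divides by the in-mask mean and is idempotent", {
  d <- c(4, 4, 3)
  mask <- array(TRUE, d)
  mp <- metric_map(array(2.5, d))
  expect_true(all(standardize_map(mp, mask)$data == 1))
  # two-voxel mask {2, 4} -> {2/3, 4/3}
  m2 <- array(0, d); m2[1, 1, 1] <- 2; m2[2, 1, 1] <- 4
  msk2 <- array(FALSE, d); msk2[1:2, 1, 1] <- TRUE
  s2 <- standardize_map(metric_map(m2), msk2)
  expect_equal(s2$data[1, 1, 1], 2 / 3, tolerance = 1e-12)
  expect_equal(s2$data[2, 1, 1], 4 / 3, tolerance = 1e-12)
  set.seed(30)
  mp3 <- metric_map(array(runif(prod(d)) + 0.5, d))
  s3 <- standardize_map(mp3, mask)
  expect_equal(mean(s3$data[mask]), 1, tolerance = 1e-12)
  expect_equal(standardize_map(s3, mask)$data, s3$data, tolerance = 1e-12)
  expect_error(standardize_map(metric_map(array(0, d)), mask), "zero")
})

test_that("Gaussian smoothing matches dense convolution and normalizes", {
  set.seed(31)
  x <- array(rnorm(9^3), c(9, 9, 9))
  mp <- metric_map(x)
  expect_identical(gaussian_smooth(mp, 0)$data, x)
  # unit impulse: mass preserved
  imp <- array(0, c(9, 9, 9)); imp[5, 5, 5] <- 1
  sm <- gaussian_smooth(metric_map(imp), fwhm_mm = 4, voxel_size_mm = 3)
  expect_equal(sum(sm$data), 1, tolerance = 1e-9)
  # brute-force dense convolution oracle
  sm2 <- gaussian_smooth(mp, fwhm_mm = 4, voxel_size_mm = 3)
  expect_equal(sm2$data, oracle_conv3d(x, 4, 3), tolerance = 1e-8)
  expect_error(gaussian_smooth(mp, -1), ">= 0")
})

test_that("group gray-matter mask thresholds the mean probability map", {
  d <- c(3, 3, 2)
  expect_true(all(build_group_gm_mask(list(array(0.5, d), array(0.5, d)), 0.2)))
  expect_false(any(build_group_gm_mask(list(array(0.1, d)), 0.2)))
  # mean of {0.1, 0.4} = 0.25 >= 0.2
  expect_true(all(build_group_gm_mask(list(array(0.1, d), array(0.4, d)), 0.2)))
  expect_error(build_group_gm_mask(list(array(0.5, d), array(0.5, c(3, 3, 3))),
                                   0.2), "common grid")
})

test_that("band-pass filter attenuates out-of-band and passes in-band", {
  n <- 400; tr <- 2
  t_s <- seq_len(n) * tr
  inband <- sin(2 * pi * 0.05 * t_s)
  outband <- sin(2 * pi * 0.2 * t_s)
  fi <- bandpass_filter(inband, tr)
  fo <- bandpass_filter(outband, tr)
  mid <- 100:300
  expect_gt(sd(fi[mid]) / sd(inband[mid]), 0.9)
  expect_lt(sd(fo[mid]) / sd(outband[mid]), 0.05)
  # agrees closely with the reference zero-phase filter away from edges
  set.seed(32)
  x <- rnorm(n)
  bf <- signal::butter(4, c(0.01, 0.1) / (1 / (2 * tr)), type = "pass")
  ref <- signal::filtfilt(bf, x)
  expect_gt(cor(bandpass_filter(x, tr)[mid], ref[mid]), 0.999)
})

test_that("the full single-subject chain is deterministic and standardized", {
  cfg <- desk_cohort_config(seed = 5, grid_dim = c(8, 8, 6), n_volumes = 60)
  subj <- generate_cohort(cfg)
  fm <- generate_fmri(subj[1, ], cfg)
  mask <- fm$gm_prob >= 0.5
  r1 <- process_fmri_subject(fm$volume, fm$motion, mask)
  r2 <- process_fmri_subject(fm$volume, fm$motion, mask)
  expect_identical(r1$falff$data, r2$falff$data)
  expect_identical(r1$reho$data, r2$reho$data)
  expect_equal(mean(r1$falff$data[mask]), 1, tolerance = 1e-9)
  expect_equal(mean(r1$reho$data[mask]), 1, tolerance = 1e-9)
  expect_true(r1$falff$standardized && r1$reho$standardized)
})
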