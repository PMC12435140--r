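# Two-stage regression engine: single fits, permutation FWE, nesting,
# peaks, group-pair scans.

test_that("fit_mlr recovers exact and random designs", {
  set.seed(51)
  n <- 30
  cv <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, c("age", "sex", "edu")))
  x <- rnorm(n)
  fit <- fit_mlr(2 * x, x, cv)
  expect_equal(fit$beta[["x_obj"]], 2, tolerance = 1e-10)
  expect_lt(fit$p, 1e-12)
  # 8-observation hand dataset vs normal equations
  y8 <- c(3.1, 2.0, 4.4, 5.2, 1.8, 6.0, 3.3, 4.1)
  x8 <- c(1, 0, 2, 3, -1, 4, 1, 2)
  z8 <- c(0.5, 1.2, -0.3, 0.8, 1.1, -0.6, 0.2, 0.9)
  fit8 <- fit_mlr(y8, x8, cbind(z = z8))
  or8 <- oracle_ols(y8, cbind(1, x8, z8))
  expect_equal(unname(fit8$beta), or8$beta, tolerance = 1e-10)
  expect_equal(unname(fit8$se), or8$se, tolerance = 1e-10)
  expect_equal(fit8$df, or8$df)
  expect_error(fit_mlr(y8, x8, cbind(a = z8, b = 2 * z8)), "collinear.*b")
  expect_error(fit_mlr(c(y8, NA), c(x8, 1)), "missing")
})

test_that("fit_mlr matches the normal-equations oracle on random instances", {
  set.seed(52)
  for (i in 1:40) {
    n <- sample(15:60, 1)
    k <- sample(1:5, 1)
    cv <- matrix(rnorm(n * k), n, k)
    x <- rnorm(n)
    y <- rnorm(n)
    fit <- fit_mlr(y, x, cv)
    or <- oracle_ols(y, cbind(1, x, cv))
    expect_equal(unname(fit$beta), or$beta, tolerance = 1e-8)
    expect_equal(fit$t, or$beta[2] / or$se[2], tolerance = 1e-8)
  }
})

test_that("fit_mlr p-values are calibrated under the null", {
  set.seed(53)
  n <- 40
  p <- replicate(1000, {
    cv <- matrix(rnorm(n * 2), n, 2)
    fit_mlr(rnorm(n), rnorm(n), cv)$p
  })
  expect_lt(abs(mean(p < 0.05) - 0.05), 2 * sqrt(0.05 * 0.95 / 1000) + 0.005)
  expect_gt(ks.test(p, "punif")$p.value, 0.01)
})

test_that("adding an uncorrelated covariate barely moves beta1 at large n", {
  set.seed(54)
  n <- 3000
  x <- rnorm(n)
  y <- 1.5 * x + rnorm(n)
  junk <- rnorm(n)
  f1 <- fit_mlr(y, x)
  f2 <- fit_mlr(y, x, cbind(junk = junk))
  expect_lt(abs(f1$beta[["x_obj"]] - f2$beta[["x_obj"]]),
            2 * f1$se[["x_obj"]])
})

test_that("voxel-wise t statistics equal per-voxel full-model fits", {
  set.seed(55)
  n <- 40; V <- 25
  X <- matrix(rnorm(n * V), n, V)
  cv <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- rnorm(n) + 0.8 * X[, 7]
  s1 <- stage1_voxelwise(X, y, cv, alpha = 1, n_perm = 120, seed = 1)
  t_direct <- sapply(seq_len(V), function(v) fit_mlr(y, X[, v], cv)$t)
  expect_equal(s1$t, t_direct, tolerance = 1e-8)
  # alpha = 1 selects everything
  expect_true(all(s1$selected))
  expect_warning(stage1_voxelwise(X, y, cv, n_perm = 50, seed = 1), "n_perm")
})

test_that("region-wise stage 1 enforces the strict Bonferroni boundary", {
  set.seed(56)
  n <- 80
  thick <- matrix(rnorm(n * 62, 2.5, 0.1), n, 62,
                  dimnames = list(NULL, dkt_labels()))
  cv <- matrix(rnorm(n * 2), n, 2, dimnames = list(NULL, c("age", "etiv")))
  y <- rnorm(n, 0, 0.5) + 4 * thick[, 10]
  s1 <- stage1_roiwise(thick, y, cv)
  expect_true(s1$selected[10])
  # boundary: threshold equal to an observed p must NOT select it
  pj <- s1$p[20]
  s1b <- stage1_roiwise(thick, y, cv, threshold = pj)
  expect_false(s1b$selected[20])
  bad <- thick[, 1:60]
  expect_error(stage1_roiwise(bad, y, cv), "missing DKT regions")
})

test_that("stage 2 is confined to the stage-1 domain and handles empties", {
  set.seed(57)
  n <- 50; V <- 30
  X <- matrix(rnorm(n * V), n, V)
  cv <- matrix(rnorm(n * 2), n, 2, dimnames = list(NULL, c("age", "sex")))
  y <- rnorm(n)
  s1 <- stage1_voxelwise(X, y, cv, alpha = 0.05, n_perm = 200, seed = 2)
  if (!sum(s1$selected)) {
    expect_warning(s2 <- stage2(X, rnorm(n), cv, s1, n_perm = 200, seed = 3),
                   "empty")
    expect_equal(sum(s2$selected), 0)
  }
  # force a stage-1 set, then a biometric exactly linear in the metric
  shared <- rnorm(n)
  X2 <- X; X2[, 5:9] <- shared + matrix(rnorm(n * 5, 0, 1e-6), n, 5)
  y2 <- 2 * shared + rnorm(n, 0, 0.1)
  s1f <- stage1_voxelwise(X2, y2, cv, alpha = 0.05, n_perm = 200, seed = 4)
  expect_true(any(s1f$selected[5:9]))
  bio <- 3 * shared
  s2f <- stage2(X2, bio, cv, s1f, alpha = 0.05, n_perm = 200, seed = 5)
  expect_true(all(which(s2f$selected) %in% which(s1f$selected)))
  expect_true(all(s2f$selected[s1f$selected & seq_len(V) %in% 5:9]))
  expect_true(all(is.na(s2f$t[!s1f$selected])))
})

test_that("find_peak takes the max |t| with first-index tie-breaking", {
  mk <- function(t, sel) cebconn:::new_significance_mask(
    "voxel", sel, t, rep(0.01, length(t)), "test", "stage2",
    voxel_idx = seq_along(t), grid_dim = c(length(t), 1, 1))
  one <- mk(c(0, 3, 0), c(FALSE, TRUE, FALSE))
  expect_equal(find_peak(one)$index, 2)
  tie <- mk(c(-4, 2, 4), c(TRUE, TRUE, TRUE))
  expect_equal(find_peak(tie)$index, 1)   # |−4| ties |4|, lower index wins
  set.seed(58)
  t <- rnorm(50); sel <- runif(50) > 0.4
  pk <- find_peak(mk(t, sel))
  expect_equal(pk$index, which(sel)[which.max(abs(t[sel]))])
  expect_error(find_peak(mk(t, rep(FALSE, 50))), "no selected")
})

test_that("stage-2 detection power is monotone in the planted slope", {
  set.seed(59)
  n <- 76; V <- 40
  detect_rate <- sapply(c(0, 0.4, 1.2), function(slope) {
    mean(replicate(50, {
      eta <- rnorm(n)
      X <- matrix(rnorm(n * V), n, V)
      X[, 3] <- X[, 3] + 1.2 * eta
      y <- 1.2 * eta + rnorm(n)
      bio <- slope * eta + rnorm(n)
      cv <- matrix(rnorm(n * 2), n, 2, dimnames = list(NULL, c("age", "sex")))
      s1 <- stage1_voxelwise(X, y, cv, n_perm = 150, seed = sample.int(1e6, 1))
      if (!sum(s1$selected)) return(FALSE)
      s2 <- stage2(X, bio, cv, s1, n_perm = 150, seed = sample.int(1e6, 1))
      s2$selected[3]
    }))
  })
  expect_true(all(diff(detect_rate) >= -0.05))   # non-decreasing up to MC noise
  expect_gt(detect_rate[3], detect_rate[1])
})

test_that("group-pair scans are deterministic and validate their inputs", {
  cfg <- desk_cohort_config(seed = 11, grid_dim = c(8, 8, 6), n_volumes = 60)
  subj <- generate_cohort(cfg)
  brain <- cohort_brain_maps(cfg, subj, channels = "falff")
  bio <- cohort_retina_biometrics(cfg, subj, measure_rbvc = FALSE)
  subj2 <- cbind(subj[, setdiff(names(subj), names(bio))], bio)
  rep1 <- run_group_pair_analysis(subj2, falff = brain$falff,
                                  pair = c("HC", "MCI"), scores = "BDST",
                                  biometrics = "faz_area_mm2",
                                  n_perm = 150, seed = 3)
  rep2 <- run_group_pair_analysis(subj2, falff = brain$falff,
                                  pair = c("HC", "MCI"), scores = "BDST",
                                  biometrics = "faz_area_mm2",
                                  n_perm = 150, seed = 3)
  expect_identical(rep1$results$falff$BDST$stage1$t,
                   rep2$results$falff$BDST$stage1$t)
  expect_equal(rep1$n, sum(subj$group %in% c("HC", "MCI")))
  expect_error(run_group_pair_analysis(subj2, falff = brain$falff,
                                       pair = c("HC", "XX")), "absent")
})
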