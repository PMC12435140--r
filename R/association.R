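# Two-stage multivariable linear regression linking cognition and
# ophthalmic biometrics to brain metrics:
#   Y = b0 + b1 x_obj + b2 age + b3 sex + b4 edu + b5 hyp + b6 dia
#       [+ b7 ETIV for cortical-thickness analyses]
# Stage 1 regresses a cognitive score on each voxel's metric (or each
# DKT region's thickness) within the gray-matter mask; family-wise error
# over voxels is controlled by permutation of the max-|t| statistic
# (Freedman-Lane residual permutation) at alpha = 0.05, and over regions
# by Bonferroni (p < 1/62, strict). Stage 2 regresses each ophthalmic
# biometric on the metric only within the stage-1 significant set, with
# correction over that reduced domain.

#' Multivariable linear regression for one predictor of interest
#'
#' Ordinary least squares of `y` on an intercept, the predictor of
#' interest `x_obj`, and the covariates. The reported `t` and `p` are for
#' the `x_obj` coefficient (two-sided, t distribution on the residual df).
#'
#' @param y Numeric response vector (a cognitive score or an ophthalmic
#'   biometric). No missing values: drop incomplete subjects upstream.
#' @param x_obj Numeric predictor of interest (a voxel metric or a
#'   region thickness).
#' @param covariates Optional numeric matrix/data frame of covariates
#'   (age, sex, education, hypertension, diabetes, and ETIV for
#'   structural analyses).
#' @return List of class `regression_fit`: `beta` (named, intercept
#'   first, then `x_obj`, then covariates), `se`, `t`, `p`, `n`, `df`.
#' @export
fit_mlr <- function(y, x_obj, covariates = NULL) {
  y <- as.numeric(y)
  n <- length(y)
  if (length(x_obj) != n)
    stop("fit_mlr: y and x_obj lengths differ", call. = FALSE)
  X <- cbind(intercept = rep(1, n), x_obj = as.numeric(x_obj))
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    if (nrow(covariates) != n)
      stop("fit_mlr: covariates row count differs from y", call. = FALSE)
    if (is.null(colnames(covariates)))
      colnames(covariates) <- paste0("cov", seq_len(ncol(covariates)))
    X <- cbind(X, covariates)
  }
  if (anyNA(X) || anyNA(y))
    stop("fit_mlr: missing values; apply listwise deletion upstream",
         call. = FALSE)
  k <- ncol(X)
  if (n <= k + 1L)
    stop("fit_mlr: too few observations for the design", call. = FALSE)
  qrX <- qr(X)
  if (qrX$rank < k) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1L):k]]
    stop("fit_mlr: collinear design columns: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  beta <- qr.coef(qrX, y)
  res <- qr.resid(qrX, y)
  df <- n - k
  sigma2 <- sum(res^2) / df
  XtXinv <- chol2inv(qr.R(qrX))
  # chol2inv of R gives (X'X)^{-1} in pivoted order; map back
  se <- sqrt(diag(XtXinv) * sigma2)[order(qrX$pivot)]
  names(se) <- names(beta)
  tval <- beta[["x_obj"]] / se[["x_obj"]]
  structure(list(beta = beta, se = se, t = tval,
                 p = 2 * stats::pt(abs(tval), df, lower.tail = FALSE),
                 n = n, df = df),
            class = "regression_fit")
}

#' @export
print.regression_fit <- function(x, ...) {
  cat(sprintf("<regression_fit> n = %d, df = %d, b1 = %.4g, t = %.3f, p = %.3g\n",
              x$n, x$df, x$beta[["x_obj"]], x$t, x$p))
  invisible(x)
}

# Vectorized per-element OLS t for the predictor of interest via
# Frisch-Waugh: residualize both Y and every column of X against the
# covariate block Z (with intercept); the simple-regression t of the
# residualized pair equals the full-model t for x_obj, with
# df = n - ncol(Z) - 1.
fw_tstats <- function(yres, Xres, sxx, df) {
  sxy <- as.vector(crossprod(Xres, yres))
  b <- ifelse(sxx > 0, sxy / sxx, 0)
  rss <- pmax(sum(yres^2) - b * sxy, 0)
  se <- sqrt(pmax(rss, 1e-300) / df / pmax(sxx, 1e-300))
  ifelse(sxx > 0, b / se, 0)
}

# A covariate column with zero variance (e.g., no diabetic subject in a
# small pooled sample) carries no information and would alias the
# intercept; the scan engines drop it with a warning.
drop_constant_covariates <- function(Z) {
  if (is.null(Z)) return(NULL)
  Z <- as.matrix(Z)
  const <- apply(Z, 2L, function(col) stats::sd(col) == 0)
  if (any(const)) {
    nm <- colnames(Z)
    if (is.null(nm)) nm <- paste0("cov", seq_len(ncol(Z)))
    warning("dropping constant covariate column(s): ",
            paste(nm[const], collapse = ", "))
    Z <- Z[, !const, drop = FALSE]
    if (!ncol(Z)) return(NULL)
  }
  Z
}

# Permutation max-|t| engine (Freedman-Lane). Y: response vector;
# X: n x V matrix of candidate predictors; Z: covariates (no intercept
# column needed; one is added). Returns observed t, FWE-adjusted p, and
# the permutation max-|t| draw.
perm_maxT <- function(y, X, Z = NULL, n_perm = 1000) {
  n <- length(y)
  Z <- drop_constant_covariates(Z)
  Zfull <- cbind(rep(1, n), Z)
  qz <- qr(Zfull)
  if (qz$rank < ncol(Zfull))
    stop("perm_maxT: collinear covariates", call. = FALSE)
  df <- n - ncol(Zfull) - 1L
  if (df < 1L) stop("perm_maxT: no residual degrees of freedom", call. = FALSE)
  yres <- qr.resid(qz, y)
  Xres <- qr.resid(qz, X)
  sxx <- colSums(Xres^2)
  t_obs <- fw_tstats(yres, Xres, sxx, df)
  maxT <- numeric(n_perm)
  for (p in seq_len(n_perm)) {
    yp <- qr.resid(qz, yres[sample.int(n)])
    maxT[p] <- max(abs(fw_tstats(yp, Xres, sxx, df)))
  }
  p_fwe <- (1 + vapply(abs(t_obs), function(tv) sum(maxT >= tv), 1)) /
    (n_perm + 1)
  list(t = t_obs, beta = ifelse(sxx > 0, as.vector(crossprod(Xres, yres)) / sxx, 0),
       p_fwe = p_fwe, maxT = maxT, df = df)
}

new_significance_mask <- function(domain, selected, t, p, correction, stage,
                                  labels = NULL, voxel_idx = NULL,
                                  grid_dim = NULL, affine = NULL,
                                  beta = NULL) {
  structure(list(domain = domain, selected = selected, t = t, p = p,
                 beta = beta, correction = correction, stage = stage,
                 labels = labels, voxel_idx = voxel_idx,
                 grid_dim = grid_dim, affine = affine),
            class = "significance_mask")
}

#' @export
print.significance_mask <- function(x, ...) {
  cat(sprintf("<significance_mask> %s %s: %d of %d selected (%s)\n",
              x$stage, x$domain, sum(x$selected), length(x$selected),
              x$correction))
  invisible(x)
}

#' Stage-1 voxel-wise association with permutation FWE control
#'
#' Per in-mask voxel, fits the multivariable model with the voxel's
#' metric as the predictor of interest and the cognitive score as the
#' response, then controls the family-wise error over voxels with the
#' permutation distribution of max |t| under Freedman-Lane residual
#' permutation. A voxel is selected when its FWE-adjusted p-value
#' `(1 + #{max-|t| perms >= |t|}) / (n_perm + 1)` is `<= alpha`.
#'
#' @param metric n_subjects x V matrix of voxel metrics (columns =
#'   in-mask voxels), or a list of [metric_map()]s with `gm_mask`.
#' @param score Cognitive score vector (response).
#' @param covariates Covariate matrix (age, sex, education, hypertension,
#'   diabetes).
#' @param gm_mask 3D logical gray-matter mask (required for map input).
#' @param alpha FWE level (default 0.05).
#' @param n_perm Number of permutations (default 1000; < 100 warns).
#' @param seed Integer seed for the permutation stream.
#' @param voxel_idx,grid_dim,affine Optional geometry for matrix input
#'   (linear voxel indices of the columns, grid dimensions, affine), so
#'   peak locations can be reported in voxel/world coordinates.
#' @return A `significance_mask` with per-voxel `t`, FWE p, selection.
#' @export
stage1_voxelwise <- function(metric, score, covariates = NULL,
                             gm_mask = NULL, alpha = 0.05, n_perm = 1000,
                             seed = 1, voxel_idx = NULL, grid_dim = NULL,
                             affine = NULL) {
  if (n_perm < 100)
    warning("stage1_voxelwise: n_perm < 100 gives a coarse FWE threshold")
  if (is.list(metric) && inherits(metric[[1L]], "metric_map")) {
    if (is.null(gm_mask))
      stop("stage1_voxelwise: gm_mask required with metric-map input",
           call. = FALSE)
    gm_mask <- check_mask(gm_mask, dim(metric[[1L]]$data))
    grid_dim <- dim(gm_mask)
    voxel_idx <- which(gm_mask)
    affine <- metric[[1L]]$affine
    metric <- do.call(rbind, lapply(metric, function(m) m$data[voxel_idx]))
  }
  metric <- as.matrix(metric)
  set.seed(seed)
  pm <- perm_maxT(score, metric, covariates, n_perm = n_perm)
  new_significance_mask("voxel", pm$p_fwe <= alpha, pm$t, pm$p_fwe,
                        sprintf("permutation max-|t| FWE, alpha = %g, %d perms",
                                alpha, n_perm),
                        "stage1", voxel_idx = voxel_idx, grid_dim = grid_dim,
                        affine = affine, beta = pm$beta)
}

#' Stage-1 region-wise association with Bonferroni control
#'
#' Per DKT region, fits the model with the region's cortical thickness as
#' predictor and the cognitive score as response; a region is selected
#' when `p < threshold` (strict; default 1/62).
#'
#' @param thickness n_subjects x 62 matrix with DKT labels as column names.
#' @param score Cognitive score vector.
#' @param covariates Covariate matrix including ETIV.
#' @param threshold Bonferroni threshold (default `1/62`).
#' @return A `significance_mask` over regions.
#' @export
stage1_roiwise <- function(thickness, score, covariates = NULL,
                           threshold = 1 / 62) {
  thickness <- as.matrix(thickness)
  expected <- dkt_labels()
  if (is.null(colnames(thickness)))
    stop("stage1_roiwise: thickness matrix must have DKT labels as column names",
         call. = FALSE)
  missing_rois <- setdiff(expected, colnames(thickness))
  if (length(missing_rois))
    stop("stage1_roiwise: missing DKT regions: ",
         paste(utils::head(missing_rois, 5), collapse = ", "),
         if (length(missing_rois) > 5) ", ..." else "", call. = FALSE)
  thickness <- thickness[, expected, drop = FALSE]
  covariates <- drop_constant_covariates(covariates)
  fits <- apply(thickness, 2L, function(x) fit_mlr(score, x, covariates))
  t <- vapply(fits, `[[`, 1, "t")
  p <- vapply(fits, `[[`, 1, "p")
  beta <- vapply(fits, function(f) f$beta[["x_obj"]], 1)
  new_significance_mask("roi", p < threshold, t, p,
                        sprintf("Bonferroni, p < %g", threshold),
                        "stage1", labels = expected, beta = beta)
}

#' Stage-2 association within the stage-1 significant set
#'
#' Fits the model with the ophthalmic biometric as the response and the
#' brain metric as predictor, only for the elements selected in stage 1;
#' correction is applied over the reduced domain (permutation max-|t| FWE
#' for voxels, Bonferroni `1/|domain|` for regions). An empty stage-1 set
#' yields an empty result with a warning.
#'
#' @param metric n_subjects x V matrix aligned with the stage-1 domain
#'   (same columns as stage 1 saw).
#' @param biometric Ophthalmic biometric vector (response).
#' @param covariates Covariate matrix.
#' @param stage1_mask `significance_mask` from stage 1.
#' @param alpha FWE level for the voxel domain.
#' @param n_perm Permutations for the voxel domain.
#' @param seed Integer seed.
#' @return A `significance_mask` with stage `"stage2"`, defined on the
#'   same full domain as stage 1 (non-tested elements carry `NA` t/p and
#'   `FALSE` selection).
#' @export
stage2 <- function(metric, biometric, covariates = NULL, stage1_mask,
                   alpha = 0.05, n_perm = 1000, seed = 1) {
  stopifnot(inherits(stage1_mask, "significance_mask"))
  V <- length(stage1_mask$selected)
  sel1 <- which(stage1_mask$selected)
  t_full <- rep(NA_real_, V); p_full <- rep(NA_real_, V)
  b_full <- rep(NA_real_, V)
  chosen <- rep(FALSE, V)
  if (!length(sel1)) {
    warning("stage2: empty stage-1 mask; returning empty result")
  } else {
    metric <- as.matrix(metric)
    if (ncol(metric) != V)
      stop("stage2: metric columns must match the stage-1 domain",
           call. = FALSE)
    sub <- metric[, sel1, drop = FALSE]
    if (stage1_mask$domain == "voxel") {
      set.seed(seed)
      pm <- perm_maxT(biometric, sub, covariates, n_perm = n_perm)
      t_full[sel1] <- pm$t; p_full[sel1] <- pm$p_fwe
      b_full[sel1] <- pm$beta
      chosen[sel1] <- pm$p_fwe <= alpha
      corr <- sprintf("permutation max-|t| FWE over %d voxels, alpha = %g",
                      length(sel1), alpha)
    } else {
      thr <- 1 / length(sel1)
      covariates <- drop_constant_covariates(covariates)
      fits <- apply(sub, 2L, function(x) fit_mlr(biometric, x, covariates))
      t_full[sel1] <- vapply(fits, `[[`, 1, "t")
      p_full[sel1] <- vapply(fits, `[[`, 1, "p")
      b_full[sel1] <- vapply(fits, function(f) f$beta[["x_obj"]], 1)
      chosen[sel1] <- p_full[sel1] < thr
      corr <- sprintf("Bonferroni over %d regions, p < %g", length(sel1), thr)
    }
  }
  out <- new_significance_mask(stage1_mask$domain, chosen, t_full, p_full,
                               if (length(sel1)) corr else "empty stage-1 domain",
                               "stage2", labels = stage1_mask$labels,
                               voxel_idx = stage1_mask$voxel_idx,
                               grid_dim = stage1_mask$grid_dim,
                               affine = stage1_mask$affine, beta = b_full)
  stopifnot(all(which(out$selected) %in% sel1))   # nesting invariant
  out
}

#' Peak location of a significance mask
#'
#' The selected element with maximum |t|; ties broken by the smallest
#' linear index. For voxel domains the voxel index and world (mm)
#' coordinate are reported; for region domains, the DKT label.
#'
#' @param mask A `significance_mask` with at least one selected element.
#' @return List with `index`, `t`, and `label` (regions) or
#'   `voxel`/`world_mm` (voxels).
#' @export
find_peak <- function(mask) {
  stopifnot(inherits(mask, "significance_mask"))
  sel <- which(mask$selected)
  if (!length(sel))
    stop("find_peak: no selected elements", call. = FALSE)
  best <- sel[which.max(abs(mask$t[sel]))]   # which.max takes first tie
  out <- list(index = best, t = mask$t[best])
  if (mask$domain == "roi") {
    out$label <- mask$labels[best]
  } else if (!is.null(mask$voxel_idx)) {
    lin <- mask$voxel_idx[best]
    vox <- arrayInd(lin, mask$grid_dim)
    out$voxel <- as.integer(vox)
    if (!is.null(mask$affine))
      out$world_mm <- as.vector(mask$affine %*% c(vox - 1L, 1))[1:3]
  }
  out
}

#' Build the covariate matrix for the association models
#'
#' @param subjects Data frame with `age`, `sex`, `education`,
#'   `hypertension`, `diabetes`, and `etiv` columns.
#' @param include_etiv Add ETIV (structural analyses only).
#' @return Numeric matrix with named columns.
#' @export
covariate_matrix <- function(subjects, include_etiv = FALSE) {
  cols <- c("age", "sex", "education", "hypertension", "diabetes")
  if (include_etiv) cols <- c(cols, "etiv")
  missing_cols <- setdiff(cols, names(subjects))
  if (length(missing_cols))
    stop("covariate_matrix: missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  as.matrix(subjects[, cols])
}

#' Two-stage analysis for one HC + patient-group pair
#'
#' Pools the HC group with one patient group (the pooled sample is a
#' single regression sample; group label is not a covariate) and runs the
#' full two-stage scan: stage 1 over every cognitive score for each brain
#' channel (FALFF, ReHo voxel-wise; thickness region-wise), and stage 2
#' over every ophthalmic biometric within each surviving stage-1 set.
#'
#' @param subjects Cohort subjects data frame (`group`, covariates,
#'   cognitive scores, biometric columns).
#' @param falff,reho n_subjects x V voxel metric matrices (rows aligned
#'   with `subjects`), or NULL to skip the channel.
#' @param thickness n_subjects x 62 thickness matrix (DKT column names),
#'   or NULL.
#' @param pair Character vector `c("HC", <patient group>)`.
#' @param scores Cognitive score column names.
#' @param biometrics Ophthalmic biometric column names.
#' @param alpha,n_perm,seed FWE parameters for the voxel domains.
#' @return Nested list: per channel, per score, the stage-1 mask and per
#'   biometric stage-2 results (mask, peak, sign of the metric coefficient
#'   at the peak).
#' @export
run_group_pair_analysis <- function(subjects, falff = NULL, reho = NULL,
                                    thickness = NULL, pair = c("HC", "MCI"),
                                    scores = c("MMSE", "MoCA", "BNT", "CDT",
                                               "BDST", "TMT_A", "TMT_B"),
                                    biometrics = c("faz_area_mm2",
                                                   "faz_perimeter_mm",
                                                   "rbvc_per_px",
                                                   "rnfl_um", "gcl_ipl_um"),
                                    alpha = 0.05, n_perm = 1000, seed = 1) {
  if (!all(pair %in% subjects$group))
    stop("run_group_pair_analysis: group(s) absent from cohort: ",
         paste(setdiff(pair, subjects$group), collapse = ", "), call. = FALSE)
  keep <- subjects$group %in% pair
  sub <- subjects[keep, , drop = FALSE]
  channels <- list()
  if (!is.null(falff)) channels$falff <- list(mat = falff[keep, , drop = FALSE],
                                              domain = "voxel")
  if (!is.null(reho)) channels$reho <- list(mat = reho[keep, , drop = FALSE],
                                            domain = "voxel")
  if (!is.null(thickness)) channels$thickness <-
      list(mat = thickness[keep, , drop = FALSE], domain = "roi")
  report <- list(pair = pair, n = nrow(sub), results = list())
  for (ch in names(channels)) {
    cv <- covariate_matrix(sub, include_etiv = (ch == "thickness"))
    for (sc in scores) {
      s1 <- if (channels[[ch]]$domain == "voxel") {
        stage1_voxelwise(channels[[ch]]$mat, sub[[sc]], cv, alpha = alpha,
                         n_perm = n_perm, seed = seed)
      } else {
        stage1_roiwise(channels[[ch]]$mat, sub[[sc]], cv)
      }
      entry <- list(stage1_n_selected = sum(s1$selected), stage1 = s1,
                    stage2 = list())
      if (sum(s1$selected) > 0) {
        for (bm in biometrics) {
          if (!bm %in% names(sub)) next
          s2 <- stage2(channels[[ch]]$mat, sub[[bm]], cv, s1, alpha = alpha,
                       n_perm = n_perm, seed = seed + 1L)
          res <- list(n_selected = sum(s2$selected), mask = s2)
          if (sum(s2$selected) > 0) {
            pk <- find_peak(s2)
            res$peak <- pk
            res$beta1_sign <- sign(s2$beta[pk$index])
          }
          entry$stage2[[bm]] <- res
        }
      }
      report$results[[ch]][[sc]] <- entry
    }
  }
  report
}
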