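# Synthetic multimodal cohort generator. Emulates the cohort structure of
# a four-group ADS study (HC/SCD/MCI/AD, 16/35/18/7 by default, with the
# published sex/hypertension/diabetes rates and age summaries) and plants
# linear couplings among a latent per-subject "neural integrity" value,
# a brain signal (fMRI blob amplitude or coherence, or a DKT region's
# thickness), a cognitive score, and an ophthalmic biometric, so the
# downstream two-stage association analysis has a recoverable ground
# truth. Volumes are generated on a common grid, post-realignment and
# post-normalization by construction.

#' Planted cognition-brain-eye effect
#'
#' One latent value per subject (group mean shift + standard normal)
#' drives: (i) the brain channel at the target (in-band sinusoid amplitude
#' for `"falff-amplitude"`, shared in-band signal weight for
#' `"reho-coherence"`, or a DKT region's thickness for `"thickness"`);
#' (ii) a cognitive score, additively with the given slope; and (iii) an
#' ophthalmic biometric, additively with the given slope.
#'
#' @param latent_name Label for the latent variable.
#' @param brain_target For voxel channels, `list(center = c(x, y, z),
#'   radius = r)` in voxel units (`center = NULL` places the blob at the
#'   grid center); for `"thickness"`, a DKT label string.
#' @param brain_channel `"falff-amplitude"`, `"reho-coherence"`, or
#'   `"thickness"`.
#' @param brain_base Baseline value of the channel parameter (sinusoid
#'   amplitude in baseline-noise SD units for `"falff-amplitude"`, shared
#'   signal weight for `"reho-coherence"`; unused for `"thickness"`).
#' @param brain_slope Change in the channel parameter (signal amplitude /
#'   coherence weight / thickness in mm) per latent SD.
#' @param cognitive_target `list(score = <name>, slope = <units per SD>)`.
#' @param ocular_target `list(biometric = <name>, slope = <units per SD>)`;
#'   biometric names: `faz_area_mm2`, `rbvc_per_px`, `rnfl_um`, `gcl_ipl_um`.
#' @param group_modulation Named per-group latent mean shifts.
#' @return Object of class `planted_effect`.
#' @export
planted_effect <- function(latent_name = "integrity",
                           brain_target = list(center = NULL, radius = 2),
                           brain_channel = c("falff-amplitude",
                                             "reho-coherence", "thickness"),
                           brain_base = 2,
                           brain_slope = 0.8,
                           cognitive_target = list(score = "BDST",
                                                   slope = 1.5),
                           ocular_target = list(biometric = "faz_area_mm2",
                                                slope = -0.05),
                           group_modulation = c(HC = 0, SCD = -0.3,
                                                MCI = -1, AD = -2)) {
  brain_channel <- match.arg(brain_channel)
  for (s in c(brain_slope, cognitive_target$slope, ocular_target$slope))
    if (!is.finite(s)) stop_config("slope", "must be finite")
  if (brain_channel == "thickness" && !is.character(brain_target))
    stop_config("brain_target", "must be a DKT label for the thickness channel")
  structure(list(latent_name = latent_name, brain_target = brain_target,
                 brain_channel = brain_channel, brain_base = brain_base,
                 brain_slope = brain_slope,
                 cognitive_target = cognitive_target,
                 ocular_target = ocular_target,
                 group_modulation = group_modulation),
            class = "planted_effect")
}

default_score_config <- function() {
  # group-level score centers follow the published medians; spreads are
  # plausible clinical dispersions (continuous Gaussian, no truncation)
  list(
    means = rbind(
      HC  = c(MMSE = 29, MoCA = 25.5, BNT = 26, CDT = 4, BDST = 5,
              TMT_A = 43.5, TMT_B = 68.5),
      SCD = c(29, 26, 27, 4, 5, 45, 67),
      MCI = c(28, 23, 23.5, 4, 4, 56.5, 89.5),
      AD  = c(17, 14, 21, 1, 4, 120, 169)
    ),
    sds = c(MMSE = 1.5, MoCA = 2.5, BNT = 2.5, CDT = 0.8, BDST = 1.2,
            TMT_A = 20, TMT_B = 40),
    # mild covariate dependence, in units of the score SD
    age_coef_sd = -0.02, edu_coef_sd = 0.05
  )
}

#' Cohort configuration
#'
#' Defaults reproduce the study conditions: group sizes 16/35/18/7,
#' published per-group sex/hypertension/diabetes rates and age summaries,
#' a 20 x 20 x 12 voxel grid at 3 mm with TR = 2 s and 185 volumes, and
#' one planted effect coupling an fMRI blob, the BDST score, and FAZ area.
#'
#' @param group_sizes Named counts for HC, SCD, MCI, AD (all > 0).
#' @param effect_spec List of [planted_effect()]s (may be empty).
#' @param grid_shape `list(dim, voxel_mm, tr, n_volumes, n_discard)`.
#' @param retina_spec `list(image_size, pixel_size_mm, n_vessels,
#'   faz_base_area_mm2, vessel_amp_px, vessel_halfwidth_px,
#'   vessel_wavelength_px, rnfl_base_um, gcl_ipl_base_um,
#'   thickness_noise_um)`.
#' @param noise Channel noise levels: `fmri` (baseline SD), per-score SDs
#'   are part of `score_config`, `faz_area_mm2`, `roi_thickness_mm`.
#' @param demographics Per-group age mean/SD, male/hypertension/diabetes
#'   probabilities, education and ETIV parameters.
#' @param score_config Score means/SDs and covariate coefficients.
#' @param seed Integer seed; the whole cohort (tables and images) is a
#'   deterministic function of the config including this seed.
#' @return Object of class `cohort_config`.
#' @export
cohort_config <- function(group_sizes = c(HC = 16, SCD = 35, MCI = 18, AD = 7),
                          effect_spec = list(planted_effect()),
                          grid_shape = list(dim = c(20, 20, 12), voxel_mm = 3,
                                            tr = 2, n_volumes = 185,
                                            n_discard = 10),
                          retina_spec = list(image_size = 160,
                                             pixel_size_mm = 0.01,
                                             n_vessels = 8,
                                             faz_base_area_mm2 = 0.35,
                                             vessel_amp_px = 3,
                                             vessel_halfwidth_px = 1,
                                             vessel_wavelength_px = 45,
                                             rnfl_base_um = 95,
                                             gcl_ipl_base_um = 75,
                                             thickness_noise_um = 3),
                          noise = list(fmri = 1, faz_area_mm2 = 0.015,
                                       roi_thickness_mm = 0.08),
                          demographics = list(
                            age_mean = c(HC = 66.63, SCD = 65.91,
                                         MCI = 66.22, AD = 64.57),
                            age_sd = c(HC = 4.559, SCD = 4.161,
                                       MCI = 5.264, AD = 5.192),
                            p_male = c(HC = 5 / 16, SCD = 7 / 35,
                                       MCI = 8 / 18, AD = 3 / 7),
                            p_hypertension = c(HC = 2 / 16, SCD = 15 / 35,
                                               MCI = 5 / 18, AD = 1 / 7),
                            p_diabetes = c(HC = 2 / 16, SCD = 2 / 35,
                                           MCI = 3 / 18, AD = 0 / 7),
                            edu_mean = 12.5, edu_sd = 2.5,
                            etiv_mean = 1.45e6, etiv_sd = 1.3e5),
                          score_config = default_score_config(),
                          seed = 1) {
  if (any(group_sizes <= 0)) stop_config("group_sizes", "must all be > 0")
  if (is.null(names(group_sizes)) || !all(nzchar(names(group_sizes))))
    stop_config("group_sizes", "must be named")
  assert_scalar_positive(grid_shape$tr, "grid_shape$tr")
  assert_scalar_positive(grid_shape$voxel_mm, "grid_shape$voxel_mm")
  assert_scalar_positive(retina_spec$pixel_size_mm, "retina_spec$pixel_size_mm")
  if (grid_shape$n_volumes <= grid_shape$n_discard)
    stop_config("grid_shape$n_volumes", "must exceed n_discard")
  if (length(grid_shape$dim) != 3L || any(grid_shape$dim < 3))
    stop_config("grid_shape$dim", "must be 3 dimensions, each >= 3")
  for (eff in effect_spec) {
    if (!inherits(eff, "planted_effect"))
      stop_config("effect_spec", "must be a list of planted_effect objects")
    if (eff$brain_channel == "thickness") {
      if (!eff$brain_target %in% dkt_labels())
        stop_config("effect_spec$brain_target",
                    sprintf("unknown DKT label '%s'", eff$brain_target))
    } else if (!is.null(eff$brain_target$center)) {
      ctr <- eff$brain_target$center
      r <- eff$brain_target$radius
      if (any(ctr - r < 1) || any(ctr + r > grid_shape$dim))
        stop_config("effect_spec$brain_target", "blob lies outside the grid")
    }
    if (!all(names(group_sizes) %in% names(eff$group_modulation)))
      stop_config("effect_spec$group_modulation",
                  "must name every group in group_sizes")
  }
  structure(list(group_sizes = group_sizes, effect_spec = effect_spec,
                 grid_shape = grid_shape, retina_spec = retina_spec,
                 noise = noise, demographics = demographics,
                 score_config = score_config, seed = seed),
            class = "cohort_config")
}

#' Desk-scale cohort configuration
#'
#' The default [cohort_config()] grid (20 x 20 x 12, 185 volumes, 160 px
#' retina) emulates the acquisition geometry; this reduced configuration
#' keeps the full pipeline at a few seconds per cohort for simulation
#' studies (power and null-calibration loops), while leaving the planted
#' effect sizes and cohort structure at their defaults.
#'
#' @param seed Cohort seed.
#' @param effects `FALSE` removes all planted effects (global null).
#' @param grid_dim,n_volumes fMRI grid and series length.
#' @param image_size,pixel_size_mm Retina canvas.
#' @return A [cohort_config()].
#' @export
desk_cohort_config <- function(seed = 1, effects = TRUE,
                               grid_dim = c(12, 12, 8), n_volumes = 100,
                               image_size = 96, pixel_size_mm = 0.02) {
  cohort_config(
    effect_spec = if (effects) list(planted_effect()) else list(),
    grid_shape = list(dim = grid_dim, voxel_mm = 3, tr = 2,
                      n_volumes = n_volumes, n_discard = 10),
    retina_spec = list(image_size = image_size,
                       pixel_size_mm = pixel_size_mm, n_vessels = 8,
                       faz_base_area_mm2 = 0.35, vessel_amp_px = 3,
                       vessel_halfwidth_px = 1, vessel_wavelength_px = 45,
                       rnfl_base_um = 95, gcl_ipl_base_um = 75,
                       thickness_noise_um = 3),
    seed = seed)
}

subject_seed <- function(config, i, stream) {
  # independent, reproducible per-subject / per-stream seeds, < 2^31
  (config$seed * 97L + i * 7919L + stream * 104729L) %% 2147483647L
}

#' Generate the cohort subject table
#'
#' Draws demographics, latent effect values, cognitive scores, and the
#' target ophthalmic biometric values for every subject. Scores follow
#' `group mean + covariate effects + sum(planted slope x latent) + noise`;
#' biometric targets follow `base + slope x latent + noise`. Deterministic
#' given the config (seeded).
#'
#' @param config A [cohort_config()].
#' @return Data frame with one row per subject: `subject_id`, `group`,
#'   covariates (`age`, `sex`, `education`, `hypertension`, `diabetes`,
#'   `etiv`), cognitive scores, `latent_*` columns, and per-subject
#'   generator parameters (fMRI blob amplitude/coherence, target
#'   biometric values, scan quality).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  gs <- config$group_sizes
  groups <- rep(names(gs), gs)
  n <- length(groups)
  dem <- config$demographics
  subj <- data.frame(
    subject_id = sprintf("S%03d", seq_len(n)),
    group = groups,
    age = stats::rnorm(n, dem$age_mean[groups], dem$age_sd[groups]),
    sex = stats::rbinom(n, 1, dem$p_male[groups]),
    education = pmin(19, pmax(6, round(stats::rnorm(n, dem$edu_mean,
                                                    dem$edu_sd)))),
    hypertension = stats::rbinom(n, 1, dem$p_hypertension[groups]),
    diabetes = stats::rbinom(n, 1, dem$p_diabetes[groups]),
    etiv = stats::rnorm(n, dem$etiv_mean, dem$etiv_sd),
    stringsAsFactors = FALSE
  )
  # latents
  for (eff in config$effect_spec) {
    shift <- eff$group_modulation[groups]
    subj[[paste0("latent_", eff$latent_name)]] <-
      as.numeric(shift) + stats::rnorm(n)
  }
  # cognitive scores
  sc <- config$score_config
  for (s in colnames(sc$means)) {
    sd_s <- sc$sds[[s]]
    val <- sc$means[groups, s] +
      sc$age_coef_sd * sd_s * (subj$age - 66) +
      sc$edu_coef_sd * sd_s * (subj$education - 12) +
      stats::rnorm(n, 0, sd_s)
    for (eff in config$effect_spec)
      if (identical(eff$cognitive_target$score, s))
        val <- val + eff$cognitive_target$slope *
          subj[[paste0("latent_", eff$latent_name)]]
    subj[[s]] <- as.numeric(val)
  }
  # target ophthalmic biometrics (generators realize these in the images)
  rs <- config$retina_spec
  targets <- data.frame(
    faz_area_mm2 = stats::rnorm(n, rs$faz_base_area_mm2,
                                config$noise$faz_area_mm2),
    rbvc_amp_px = rep(rs$vessel_amp_px, n),
    rnfl_um = stats::rnorm(n, rs$rnfl_base_um, 1),
    gcl_ipl_um = stats::rnorm(n, rs$gcl_ipl_base_um, 1)
  )
  for (eff in config$effect_spec) {
    bm <- eff$ocular_target$biometric
    eta <- subj[[paste0("latent_", eff$latent_name)]]
    if (bm == "faz_area_mm2")
      targets$faz_area_mm2 <- targets$faz_area_mm2 +
        eff$ocular_target$slope * eta
    else if (bm == "rbvc_per_px")
      targets$rbvc_amp_px <- pmax(0, targets$rbvc_amp_px +
                                    eff$ocular_target$slope * eta)
    else if (bm == "rnfl_um")
      targets$rnfl_um <- targets$rnfl_um + eff$ocular_target$slope * eta
    else if (bm == "gcl_ipl_um")
      targets$gcl_ipl_um <- targets$gcl_ipl_um + eff$ocular_target$slope * eta
    else stop_config("ocular_target$biometric",
                     sprintf("unknown biometric '%s'", bm))
  }
  targets$faz_area_mm2 <- pmax(0.05, targets$faz_area_mm2)
  # fMRI channel parameters
  amp <- rep(0, n); coh <- rep(0, n)
  for (eff in config$effect_spec) {
    eta <- subj[[paste0("latent_", eff$latent_name)]]
    if (eff$brain_channel == "falff-amplitude")
      amp <- pmax(0, eff$brain_base + eff$brain_slope * eta)
    else if (eff$brain_channel == "reho-coherence")
      coh <- pmin(0.95, pmax(0, eff$brain_base + eff$brain_slope * eta))
  }
  subj$fmri_amp <- amp
  subj$fmri_coherence <- coh
  subj$quality_index <- pmax(6, pmin(10, stats::rnorm(n, 8.5, 0.6)))
  cbind(subj, targets)
}

blob_center <- function(eff, dims) {
  if (!is.null(eff$brain_target$center)) eff$brain_target$center
  else round(dims / 2)
}

blob_mask <- function(center, radius, dims) {
  g <- expand.grid(x = seq_len(dims[1]), y = seq_len(dims[2]),
                   z = seq_len(dims[3]))
  d2 <- (g$x - center[1])^2 + (g$y - center[2])^2 + (g$z - center[3])^2
  array(d2 <= radius^2, dims)
}

#' Ground-truth blob mask of the default planted effect
#'
#' @param config A [cohort_config()].
#' @return 3D logical array marking the planted fMRI blob (all-FALSE when
#'   no voxel-channel effect is planted).
#' @export
planted_blob_mask <- function(config) {
  dims <- config$grid_shape$dim
  out <- array(FALSE, dims)
  for (eff in config$effect_spec)
    if (eff$brain_channel %in% c("falff-amplitude", "reho-coherence"))
      out <- out | blob_mask(blob_center(eff, dims), eff$brain_target$radius,
                             dims)
  out
}

#' Generate one subject's synthetic fMRI run
#'
#' Gaussian baseline noise on the configured grid plus, inside the planted
#' blob, an in-band (0.05 Hz) sinusoid whose amplitude follows the
#' subject's `fmri_amp` (FALFF channel) and/or a shared band-limited
#' signal with weight `fmri_coherence` (ReHo channel). Also returns a
#' smooth gray-matter probability map (>= 0.5 inside the brain ellipsoid,
#' 0 outside) and a 6-parameter motion table simulated as a small-step
#' random walk, far below a 3 mm / 3 degree exclusion bound.
#'
#' @param subject One row of the [generate_cohort()] table.
#' @param config The [cohort_config()].
#' @return List: `volume` ([voxel_volume()]), `gm_prob` (3D array),
#'   `motion` (n_volumes x 6 matrix).
#' @export
generate_fmri <- function(subject, config) {
  gsh <- config$grid_shape
  dims <- gsh$dim
  nt <- gsh$n_volumes
  i <- as.integer(sub("^S", "", subject$subject_id))
  set.seed(subject_seed(config, i, 1L))
  vol <- array(stats::rnorm(prod(dims) * nt, 0, config$noise$fmri),
               c(dims, nt))
  tt <- seq_len(nt) * gsh$tr
  for (eff in config$effect_spec) {
    if (!eff$brain_channel %in% c("falff-amplitude", "reho-coherence")) next
    ctr <- blob_center(eff, dims)
    r <- eff$brain_target$radius
    if (any(ctr - r < 1) || any(ctr + r > dims))
      stop("generate_fmri: planted blob lies outside the grid", call. = FALSE)
    bm <- blob_mask(ctr, r, dims)
    idx <- which(bm)
    if (eff$brain_channel == "falff-amplitude") {
      # independent phase per voxel: raises in-band amplitude without
      # inducing coherence (and without leaking into the global mean)
      phases <- stats::runif(length(idx), 0, 2 * pi)
      sig <- subject$fmri_amp *
        sin(outer(phases, 2 * pi * 0.05 * tt, `+`))
      vol_flat <- matrix(vol, prod(dims), nt)
      vol_flat[idx, ] <- vol_flat[idx, ] + sig
      vol <- array(vol_flat, c(dims, nt))
    } else {
      shared <- bandpass_filter(stats::rnorm(nt), gsh$tr, c(0.01, 0.1))
      shared <- shared / stats::sd(shared)
      w <- subject$fmri_coherence
      vol_flat <- matrix(vol, prod(dims), nt)
      vol_flat[idx, ] <- sqrt(1 - w^2) * vol_flat[idx, ] +
        w * config$noise$fmri * matrix(shared, length(idx), nt, byrow = TRUE)
      vol <- array(vol_flat, c(dims, nt))
    }
  }
  # gray-matter probability: smooth radial profile inside the ellipsoid
  g <- expand.grid(x = seq_len(dims[1]), y = seq_len(dims[2]),
                   z = seq_len(dims[3]))
  ctr <- (dims + 1) / 2
  rho2 <- ((g$x - ctr[1]) / (0.48 * dims[1]))^2 +
    ((g$y - ctr[2]) / (0.48 * dims[2]))^2 +
    ((g$z - ctr[3]) / (0.48 * dims[3]))^2
  gm <- array(ifelse(rho2 <= 1, 0.6 + 0.3 * (1 - rho2), 0), dims)
  motion <- cbind(
    apply(matrix(stats::rnorm(nt * 3, 0, 0.02), nt, 3), 2, cumsum),
    apply(matrix(stats::rnorm(nt * 3, 0, 0.01), nt, 3), 2, cumsum)
  )
  colnames(motion) <- c("tx_mm", "ty_mm", "tz_mm", "rx_deg", "ry_deg",
                        "rz_deg")
  affine <- diag(c(rep(gsh$voxel_mm, 3), 1))
  list(volume = voxel_volume(vol, affine, gsh$tr), gm_prob = gm,
       motion = motion)
}

fill_ellipse <- function(size, center, a, b, angle = 0) {
  g <- expand.grid(r = seq_len(size), c = seq_len(size))
  dr <- g$r - center[1]; dc <- g$c - center[2]
  u <- dr * cos(angle) + dc * sin(angle)
  v <- -dr * sin(angle) + dc * cos(angle)
  matrix((u / a)^2 + (v / b)^2 <= 1, size, size)
}

stamp_points <- function(size, pts, halfwidth) {
  m <- matrix(FALSE, size, size)
  pts <- pts[pts[, 1] >= 1 & pts[, 1] <= size &
               pts[, 2] >= 1 & pts[, 2] <= size, , drop = FALSE]
  m[pts] <- TRUE
  if (halfwidth > 0) {
    acc <- m
    for (di in -halfwidth:halfwidth) for (dj in -halfwidth:halfwidth)
      acc <- acc | shift_mat(m, di, dj, fill = FALSE)
    m <- acc
  }
  m
}

#' Generate one subject's synthetic retinal image set
#'
#' The FAZ mask is a filled ellipse whose area matches the subject's
#' target FAZ area; the vessel mask rasterizes curves radiating from just
#' outside the FAZ to the image margin with a sinusoidal tangential
#' perturbation of amplitude `rbvc_amp_px`; thickness maps are
#' constant-plus-noise fields at the subject's target layer thicknesses.
#' Bit-identical under the same config and subject (seeded).
#'
#' @param subject One row of the [generate_cohort()] table.
#' @param config The [cohort_config()].
#' @return A [retinal_image_set()].
#' @export
generate_retina <- function(subject, config) {
  rs <- config$retina_spec
  size <- rs$image_size
  px <- rs$pixel_size_mm
  i <- as.integer(sub("^S", "", subject$subject_id))
  set.seed(subject_seed(config, i, 2L))
  ctr <- c(size / 2, size / 2)
  r_px <- sqrt(subject$faz_area_mm2 / pi) / px
  ecc <- stats::runif(1, 0.92, 1.08)
  ang <- stats::runif(1, 0, pi)
  faz <- fill_ellipse(size, ctr, r_px * ecc, r_px / ecc, ang)
  # vessels: radial curves with sinusoidal tangential perturbation
  vessel <- matrix(FALSE, size, size)
  r0 <- r_px * 1.35 + 2
  r1 <- size / 2 - 2
  if (r1 <= r0)
    stop("generate_retina: FAZ too large for the canvas", call. = FALSE)
  amp <- subject$rbvc_amp_px
  clipped <- FALSE
  for (k in seq_len(rs$n_vessels)) {
    th <- 2 * pi * (k - 1) / rs$n_vessels + stats::runif(1, -0.1, 0.1)
    phase <- stats::runif(1, 0, 2 * pi)
    s <- seq(r0, r1, by = 0.5)
    off <- amp * sin(2 * pi * s / rs$vessel_wavelength_px + phase)
    rr <- ctr[1] + s * cos(th) - off * sin(th)
    cc <- ctr[2] + s * sin(th) + off * cos(th)
    pts <- cbind(round(rr), round(cc))
    if (any(pts < 1 | pts > size)) clipped <- TRUE
    vessel <- vessel | stamp_points(size, pts, rs$vessel_halfwidth_px)
  }
  if (clipped)
    warning("generate_retina: vessel curve left the canvas and was clipped")
  thick <- list(
    RNFL = matrix(subject$rnfl_um +
                    stats::rnorm(size^2, 0, rs$thickness_noise_um),
                  size, size),
    GCL_IPL = matrix(subject$gcl_ipl_um +
                       stats::rnorm(size^2, 0, rs$thickness_noise_um),
                     size, size)
  )
  retinal_image_set(vessel, faz, thick, px, subject$quality_index)
}

#' Generate one subject's DKT cortical thickness table
#'
#' One thickness (mm) per DKT region: a fixed per-region baseline profile
#' plus Gaussian noise, with any planted `"thickness"` effect shifting its
#' target region by `brain_slope x latent`.
#'
#' @param subject One row of the [generate_cohort()] table.
#' @param config The [cohort_config()].
#' @param baseline Optional named baseline vector (62 DKT labels);
#'   default is a fixed profile in 2.2-2.8 mm.
#' @return Named numeric vector of 62 thicknesses (mm).
#' @export
generate_thickness_table <- function(subject, config, baseline = NULL) {
  labs <- dkt_labels()
  if (is.null(baseline)) {
    baseline <- 2.5 + 0.3 * sin(seq(0, 2 * pi, length.out = 62))
    names(baseline) <- labs
  }
  if (!all(labs %in% names(baseline)))
    stop_config("baseline", "must name all 62 DKT regions")
  i <- as.integer(sub("^S", "", subject$subject_id))
  set.seed(subject_seed(config, i, 3L))
  vals <- baseline[labs] +
    stats::rnorm(62, 0, config$noise$roi_thickness_mm)
  for (eff in config$effect_spec) {
    if (eff$brain_channel != "thickness") next
    eta <- subject[[paste0("latent_", eff$latent_name)]]
    vals[eff$brain_target] <- vals[eff$brain_target] + eff$brain_slope * eta
  }
  vals
}
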