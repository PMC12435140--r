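# Synthetic cohort generator: structure, determinism, planted signal.

test_that("default cohort has the study group structure", {
  cfg <- cohort_config(seed = 2)
  subj <- generate_cohort(cfg)
  expect_equal(nrow(subj), 76)
  expect_equal(as.vector(table(subj$group)[c("HC", "SCD", "MCI", "AD")]),
               c(16, 35, 18, 7))
  expect_true(all(subj$sex %in% 0:1))
  expect_true(all(subj$hypertension %in% 0:1))
  expect_true(all(subj$education >= 6 & subj$education <= 19))
  expect_true(all(subj$etiv > 0))
  expect_true(all(c("MMSE", "MoCA", "BNT", "CDT", "BDST", "TMT_A", "TMT_B")
                  %in% names(subj)))
})

test_that("the cohort is a deterministic function of config + seed", {
  cfg <- desk_cohort_config(seed = 9)
  s1 <- generate_cohort(cfg)
  s2 <- generate_cohort(cfg)
  expect_identical(s1, s2)
  f1 <- generate_fmri(s1[3, ], cfg)
  f2 <- generate_fmri(s2[3, ], cfg)
  expect_identical(f1$volume$data, f2$volume$data)
  expect_identical(f1$motion, f2$motion)
  r1 <- generate_retina(s1[3, ], cfg)
  r2 <- generate_retina(s2[3, ], cfg)
  expect_identical(r1$vessel_mask, r2$vessel_mask)
  expect_identical(r1$faz_mask, r2$faz_mask)
  t1 <- generate_thickness_table(s1[3, ], cfg)
  expect_identical(t1, generate_thickness_table(s2[3, ], cfg))
  # different seed, different cohort
  expect_false(identical(s1, generate_cohort(desk_cohort_config(seed = 10))))
})

test_that("invalid configurations fail naming the offending field", {
  expect_error(cohort_config(group_sizes = c(HC = 0, SCD = 1, MCI = 1, AD = 1)),
               "group_sizes")
  expect_error(cohort_config(grid_shape = list(dim = c(10, 10, 6), voxel_mm = 3,
                                               tr = 2, n_volumes = 10,
                                               n_discard = 10)),
               "n_volumes")
  expect_error(cohort_config(effect_spec = list(planted_effect(
    brain_target = list(center = c(1, 1, 1), radius = 3)))),
    "outside the grid")
  expect_error(cohort_config(effect_spec = list(planted_effect(
    brain_channel = "thickness", brain_target = "left hippocampus"))),
    "unknown DKT label")
})

test_that("fMRI generator honors the configured series length and geometry", {
  cfg <- cohort_config(seed = 3)
  subj <- generate_cohort(cfg)
  fm <- generate_fmri(subj[1, ], cfg)
  expect_equal(dim(fm$volume$data)[4], 185)
  expect_equal(dim(fm$volume$data)[1:3], c(20, 20, 12))
  expect_equal(dim(fm$motion), c(185, 6))
  # motion stays far below a 3 mm / 3 degree exclusion bound
  expect_lt(max(abs(fm$motion)), 1.5)
  # GM probability >= 0.5 inside the brain ellipsoid center region
  expect_gte(fm$gm_prob[10, 10, 6], 0.5)
  expect_equal(fm$gm_prob[1, 1, 1], 0)
})

test_that("planted amplitude raises in-band FALFF inside the blob", {
  cfg <- desk_cohort_config(seed = 4)
  blob <- planted_blob_mask(cfg)
  hits <- 0
  for (r in 1:10) {
    cfgr <- desk_cohort_config(seed = 300 + r)
    subj <- generate_cohort(cfgr)
    # a high-amplitude subject (HC, latent near or above 0)
    s <- subj[subj$group == "HC", ][1, ]
    fm <- generate_fmri(s, cfgr)
    mask <- fm$gm_prob >= 0.5
    maps <- process_fmri_subject(fm$volume, fm$motion, mask,
                                 channels = "falff")
    if (mean(maps$falff$data[blob]) > mean(maps$falff$data[mask & !blob]))
      hits <- hits + 1
  }
  expect_gte(hits, 9)
})

test_that("with no planted effects the blob is background", {
  cfg <- desk_cohort_config(seed = 6, effects = FALSE)
  subj <- generate_cohort(cfg)
  fm <- generate_fmri(subj[1, ], cfg)
  mask <- fm$gm_prob >= 0.5
  maps <- process_fmri_subject(fm$volume, fm$motion, mask,
                               channels = "falff")
  blob <- planted_blob_mask(desk_cohort_config(seed = 6))  # default target
  tt <- t.test(maps$falff$data[blob & mask], maps$falff$data[mask & !blob])
  expect_gt(tt$p.value, 0.05)
})

test_that("retina generator realizes the planted FAZ area and is exact on discs", {
  cfg <- desk_cohort_config(seed = 7)
  subj <- generate_cohort(cfg)
  for (i in c(1, 20, 60)) {
    img <- generate_retina(subj[i, ], cfg)
    measured <- faz_area(clean_components(img$faz_mask, 5), img$pixel_size_mm)
    expect_equal(measured, subj$faz_area_mm2[i], tolerance = 0.02)
  }
  # an extreme tortuosity amplitude leaves the canvas: clipped with warning
  sbig <- subj[1, ]; sbig$rbvc_amp_px <- 40
  expect_warning(generate_retina(sbig, cfg), "clipped")
  # straight-vessel configuration: downstream RBVC near zero
  s <- subj[1, ]; s$rbvc_amp_px <- 0
  img0 <- generate_retina(s, cfg)
  r0 <- rbvc(clean_components(img0$vessel_mask, 5), cfg$retina_spec$pixel_size_mm)
  expect_lt(r0$rbvc_per_px, 0.02)
})

test_that("thickness tables have 62 regions and honor planted shifts", {
  cfg <- desk_cohort_config(seed = 8)
  subj <- generate_cohort(cfg)
  th <- generate_thickness_table(subj[1, ], cfg)
  expect_length(th, 62)
  expect_identical(names(th), dkt_labels())
  # zero noise, zero slopes: exactly the baseline
  cfg0 <- cohort_config(effect_spec = list(),
                        noise = list(fmri = 1, faz_area_mm2 = 0.015,
                                     roi_thickness_mm = 0),
                        seed = 5)
  s0 <- generate_cohort(cfg0)
  base <- 2.5 + 0.3 * sin(seq(0, 2 * pi, length.out = 62))
  names(base) <- dkt_labels()
  expect_equal(generate_thickness_table(s0[1, ], cfg0), base,
               tolerance = 1e-15)
})

test_that("a planted thickness effect is recovered region-wise at n = 300", {
  eff <- planted_effect(brain_channel = "thickness",
                        brain_target = "rh fusiform", brain_slope = 0.12,
                        cognitive_target = list(score = "MMSE", slope = 1.5))
  hits <- 0; false_rois <- 0
  for (r in 1:25) {
    cfg <- cohort_config(group_sizes = c(HC = 75, SCD = 75, MCI = 75, AD = 75),
                         effect_spec = list(eff), seed = 500 + r)
    subj <- generate_cohort(cfg)
    thick <- cohort_thickness_matrix(cfg, subj)
    s1 <- stage1_roiwise(thick, subj$MMSE,
                         covariate_matrix(subj, include_etiv = TRUE))
    sel <- s1$labels[s1$selected]
    if ("rh fusiform" %in% sel) hits <- hits + 1
    false_rois <- false_rois + length(setdiff(sel, "rh fusiform"))
  }
  expect_gte(hits / 25, 0.9)
  # Bonferroni keeps the rest of the atlas almost always clean
  expect_lte(false_rois / 25, 1)
})
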