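# FAZ morphometry, vessel centerline curvature, layer thickness.

test_that("quality gate uses the >= 6 convention", {
  img <- retinal_image_set(matrix(TRUE, 4, 4), matrix(TRUE, 4, 4),
                           quality_index = 6)
  expect_true(quality_gate(img))
  img$quality_index <- 5.9
  expect_false(quality_gate(img))
  img$quality_index <- 10
  expect_true(quality_gate(img))
})

test_that("clean_components removes small 8-connected objects", {
  m <- matrix(FALSE, 20, 20)
  m[2, 2:4] <- TRUE                        # 3-px blob
  expect_false(any(clean_components(m, 5)))
  m2 <- matrix(FALSE, 30, 30)
  m2[5:14, 5:14] <- TRUE                   # 100 px
  m2[25, 25:28] <- TRUE                    # 4 px
  cleaned <- clean_components(m2, 5)
  expect_equal(sum(cleaned), 100)
  expect_false(cleaned[25, 25])
  expect_identical(clean_components(m2, 0), m2)
  # diagonal-only touching pixels are one component (8-connectivity)
  m3 <- matrix(FALSE, 10, 10)
  m3[cbind(2:5, 2:5)] <- TRUE
  expect_equal(max(label_components(m3)), 1)
  expect_equal(sum(clean_components(m3, 4)), 4)
})

test_that("FAZ area counts pixels of the largest component", {
  single <- matrix(FALSE, 10, 10); single[5, 5] <- TRUE
  expect_equal(faz_area(single, 0.01), 1e-4)
  # disc r = 50 px vs analytic area
  d <- disc_mask(120, c(60, 60), 50)
  expect_equal(faz_area(d, 0.01), pi * 0.25, tolerance = 0.02)
  # two components: largest wins, with a warning
  two <- matrix(FALSE, 40, 40)
  two[2:21, 2:21] <- TRUE                  # 400 px
  two[30, 30:39] <- TRUE                   # 10 px
  expect_warning(a <- faz_area(two, 0.01), "largest")
  expect_equal(a, 400 * 1e-4)
  expect_error(faz_area(matrix(FALSE, 5, 5), 0.01), "no region")
})

test_that("FAZ perimeter is the traced boundary polygon length", {
  sq <- matrix(FALSE, 14, 14); sq[3:12, 3:12] <- TRUE   # 10x10 square
  expect_equal(faz_perimeter(sq, 0.01), 0.36, tolerance = 1e-12)
  d <- disc_mask(120, c(60, 60), 50)
  expect_equal(faz_perimeter(d, 0.01), 2 * pi * 0.5, tolerance = 0.05)
  single <- matrix(FALSE, 8, 8); single[4, 4] <- TRUE
  expect_warning(p <- faz_perimeter(single, 0.01), "single-pixel")
  expect_equal(p, 0)
})

test_that("area and perimeter scale as s^2 and s with shape resolution", {
  # rasterize the same disc at s-fold resolution (pixel-block upsampling
  # would turn diagonal boundary steps into staircases, which the traced
  # polygon measures faithfully as longer)
  d <- disc_mask(90, c(45, 45), 30)
  a1 <- faz_area(d, 1); p1 <- faz_perimeter(d, 1)
  for (s in c(2, 3)) {
    up <- disc_mask(90 * s, c(45 * s, 45 * s), 30 * s)
    expect_equal(faz_area(up, 1) / a1, s^2, tolerance = 0.03)
    expect_equal(faz_perimeter(up, 1) / p1, s, tolerance = 0.03)
  }
})

test_that("vessel_boundary flags exactly the pixels touching background", {
  expect_false(any(vessel_boundary(matrix(FALSE, 6, 6))))
  single <- matrix(FALSE, 6, 6); single[3, 3] <- TRUE
  expect_identical(vessel_boundary(single), single)
  sq <- matrix(FALSE, 9, 9); sq[3:7, 3:7] <- TRUE
  b <- vessel_boundary(sq)
  expect_equal(sum(b), 16)
  expect_false(b[5, 5])
  # boundary is always a subset of the mask
  set.seed(41)
  r <- matrix(runif(400) > 0.6, 20, 20)
  expect_true(all(r[vessel_boundary(r)]))
})

test_that("centerline extraction recovers bars, junctions, and loops", {
  bar <- matrix(FALSE, 20, 60)
  bar[9:11, 5:54] <- TRUE
  paths <- extract_centerlines(bar)
  expect_length(paths, 1)
  expect_gt(nrow(paths[[1]]), 40)
  expect_true(all(paths[[1]][, 1] == paths[[1]][1, 1]))  # collinear
  expect_length(extract_centerlines(matrix(FALSE, 10, 10)), 0)
  # plus sign: four branches meeting at one junction
  plus <- matrix(FALSE, 41, 41)
  plus[20:22, 6:36] <- TRUE
  plus[6:36, 20:22] <- TRUE
  paths2 <- extract_centerlines(plus)
  expect_length(paths2, 4)
  # ring: one closed loop
  rg <- ring_mask(100, c(50, 50), 30)
  paths3 <- extract_centerlines(rg)
  expect_length(paths3, 1)
  expect_true(isTRUE(attr(paths3[[1]], "closed")))
})

test_that("path curvature matches analytic values", {
  # collinear points
  line <- cbind(1:20, 2 * (1:20))
  expect_true(all(path_curvature(line) == 0))
  # dense exact circle, radius 40
  R <- 40
  mth <- round(2 * pi * R)
  th <- seq(0, 2 * pi, length.out = mth + 1)[1:mth]
  circ <- cbind(50 + R * cos(th), 50 + R * sin(th))
  attr(circ, "closed") <- TRUE
  k <- path_curvature(circ)
  expect_equal(mean(k), 1 / R, tolerance = 0.05)
  # 5-point parabola y = x^2/2: curvature 1 at the vertex
  par5 <- cbind(-2:2, (-2:2)^2 / 2)
  k5 <- path_curvature(par5)
  expect_equal(k5[3], 1, tolerance = 0.05)
  expect_error(path_curvature(cbind(1:3, 1:3)), "at least 5")
})

test_that("RBVC: straight vessels ~ 0, circles ~ 1/R, rotation-stable", {
  m <- straight_vessel_mask()
  r0 <- rbvc(m, 0.01)
  expect_lte(r0$rbvc_per_px, 1e-3)
  expect_equal(r0$rbvc_per_mm, r0$rbvc_per_px / 0.01)
  rg <- ring_mask(120, c(60, 60), 40)
  rr <- rbvc(rg, 0.01)
  expect_equal(rr$rbvc_per_px, 1 / 40, tolerance = 0.10)
  # exact invariance under 90-degree rotation
  m90 <- t(m)[ncol(m):1, ]
  expect_equal(rbvc(m90, 0.01)$rbvc_per_px, r0$rbvc_per_px, tolerance = 1e-12)
  expect_error(rbvc(matrix(FALSE, 10, 10), 0.01), "no centerline")
})

test_that("RBVC increases with the planted tortuosity amplitude", {
  cfg <- desk_cohort_config(seed = 8)
  subj <- generate_cohort(cfg)
  means <- sapply(c(1.5, 3, 6), function(amp) {
    vals <- sapply(1:12, function(i) {
      s <- subj[i, ]; s$rbvc_amp_px <- amp
      img <- generate_retina(s, cfg)
      rbvc(clean_components(img$vessel_mask, 5), cfg$retina_spec$pixel_size_mm)$rbvc_per_px
    })
    mean(vals)
  })
  expect_true(all(diff(means) > 0))
})

test_that("layer thickness mean is the arithmetic mean over the region", {
  expect_equal(layer_thickness_mean(matrix(30, 5, 5)), 30)
  half <- rbind(matrix(20, 3, 6), matrix(40, 3, 6))
  expect_equal(layer_thickness_mean(half), 30)
  set.seed(42)
  m <- matrix(rnorm(100, 80, 5), 10, 10)
  reg <- matrix(runif(100) > 0.5, 10, 10)
  expect_equal(layer_thickness_mean(m, reg), mean(m[reg]), tolerance = 1e-12)
  expect_error(layer_thickness_mean(m, matrix(FALSE, 10, 10)), "empty")
})
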