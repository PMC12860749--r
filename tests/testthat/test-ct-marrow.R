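test_that("classify_voxel matches the printed bands at every boundary", {
  expect_identical(as.character(classify_voxel(-100)), "fat_marrow")
  expect_identical(as.character(classify_voxel(50)), "infiltrated")
  expect_identical(as.character(classify_voxel(150)), "cortical")
  expect_identical(as.character(classify_voxel(-300)), "out_of_range")
  # boundaries: fat closed at both ends, infiltrated half-open, cortical open
  expect_identical(as.character(classify_voxel(c(-200, -30, -30 + 1e-9,
                                                 120, 120 + 1e-9))),
                   c("fat_marrow", "fat_marrow", "infiltrated",
                     "infiltrated", "cortical"))
  expect_identical(as.character(classify_voxel(-200 - 1e-9)),
                   "out_of_range")
  expect_error(classify_voxel(NA_real_), "finite")
  expect_error(classify_voxel(Inf), "finite")
})

test_that("classification partitions every finite HU value", {
  hu <- seq(-500, 500, by = 0.25)
  cls <- classify_voxel(hu)
  expect_false(anyNA(cls))                       # everything classified
  expect_identical(length(cls), length(hu))      # exactly one class each
})

test_that("medullary working mask excludes epiphysis and bright voxels", {
  fx <- fixture_cylinder_ct()
  ct <- fx$ct
  # one cavity voxel pushed above cortical threshold, one exactly at 120
  i_bright <- which(fx$cavity$data)[1]
  i_edge <- which(fx$cavity$data)[2]
  ct$data[i_bright] <- 200
  ct$data[i_edge] <- 120
  epi <- fx$empty
  i_epi <- which(fx$cavity$data)[3]
  epi$data[i_epi] <- TRUE
  wm <- medullary_working_mask(ct, fx$cavity, epi)
  expect_false(wm$data[i_bright])                # HU > 120 excluded
  expect_true(wm$data[i_edge])                   # boundary 120 included
  expect_false(wm$data[i_epi])                   # epiphysis excluded
  expect_error(
    medullary_working_mask(ct, fx$cavity,
                           label_mask(array(FALSE, c(2, 2, 2)))),
    "not aligned")
})

test_that("manual CTv recovers planted homogeneous regions", {
  fx <- fixture_cylinder_ct(shape = c(24L, 24L, 24L), cavity_hu = -80,
                            radius_mm = 8)
  wm <- medullary_working_mask(fx$ct, fx$cavity, fx$empty)
  # uniform cavity: any ROI mean is the constant
  expect_equal(manual_ctv(fx$ct, wm, radii_mm = 3)$ctv, -80)

  # single 40-HU sphere (radius 5 mm): a 3-mm disc fits inside -> ctv = 40
  ct1 <- paint_sphere(fx$ct, c(12, 12, 12), 5, 40)
  res <- manual_ctv(ct1, wm, radii_mm = 3)
  expect_equal(res$ctv, 40)
  expect_equal(res$best_roi$radius_mm, 3)

  # two homogeneous regions at 20 and 35 HU -> the hotter one wins
  ct2 <- paint_sphere(fx$ct, c(12, 12, 7), 5, 20)
  ct2 <- paint_sphere(ct2, c(12, 12, 17), 5, 35)
  expect_equal(manual_ctv(ct2, wm, radii_mm = 3)$ctv, 35)
})

test_that("manual CTv equals the exhaustive-sweep oracle on noisy input", {
  set.seed(21)
  fx <- fixture_cylinder_ct(shape = c(14L, 14L, 8L), radius_mm = 5)
  fx$ct$data[fx$cavity$data] <-
    fx$ct$data[fx$cavity$data] + rnorm(sum(fx$cavity$data), 0, 30)
  wm <- medullary_working_mask(fx$ct, fx$cavity, fx$empty)
  for (r in c(2, 3.5)) {
    expect_equal(manual_ctv(fx$ct, wm, radii_mm = r)$ctv,
                 oracle_manual_ctv(fx$ct, wm, r), tolerance = 1e-12)
  }
})

test_that("manual CTv is local: voxels outside every candidate ROI are
           irrelevant, and a hotter region never lowers it", {
  fx <- fixture_cylinder_ct()
  wm <- medullary_working_mask(fx$ct, fx$cavity, fx$empty)
  ct1 <- paint_sphere(fx$ct, c(12, 12, 12), 5, 40)
  base <- manual_ctv(ct1, wm, radii_mm = 3)$ctv
  # modify voxels outside the working mask only
  ct_mod <- ct1
  ct_mod$data[!wm$data] <- 999
  expect_equal(manual_ctv(ct_mod, wm, radii_mm = 3)$ctv, base)
  # add a strictly hotter homogeneous region
  ct_hot <- paint_sphere(ct1, c(12, 12, 5), 5, 60)
  expect_gte(manual_ctv(ct_hot, wm, radii_mm = 3)$ctv, base)

  # degenerate: no ROI of the requested radius fits
  tiny <- label_mask(array(FALSE, dim(fx$ct$data)), spacing = fx$ct$spacing)
  tiny$data[12, 12, 12] <- TRUE
  expect_error(manual_ctv(fx$ct, tiny, radii_mm = 3), "degenerate")
  empty <- label_mask(array(FALSE, dim(fx$ct$data)),
                      spacing = fx$ct$spacing)
  expect_error(manual_ctv(fx$ct, empty, radii_mm = 3), "empty")
})

test_that("cCTv matches its printed examples and the literal flag", {
  # 1000-voxel cavity (1 mm^3 voxels), 200 MM voxels at 30 HU
  arr <- array(-100, c(10, 10, 10))
  arr[1:200] <- 30
  ct <- volume_grid(arr, units = "HU")
  wm <- label_mask(array(TRUE, c(10, 10, 10)))
  res <- compute_cctv(ct, wm)
  expect_equal(res$cctv, 200 * 30 / 1000)        # 6.0 HU
  expect_equal(res$mm_volume_mm3, 200)
  expect_equal(res$cavity_volume_mm3, 1000)
  # literal reading: HU sum x volume ratio
  lit <- compute_cctv(ct, wm, interpretation = "literal")
  expect_equal(lit$cctv, 6000 * 200 / 1000)

  # no MM voxels -> 0; all-MM constant field -> the constant
  ct0 <- volume_grid(array(-100, c(10, 10, 10)), units = "HU")
  expect_equal(compute_cctv(ct0, wm)$cctv, 0)
  ctc <- volume_grid(array(42, c(10, 10, 10)), units = "HU")
  expect_equal(compute_cctv(ctc, wm)$cctv, 42)

  expect_error(compute_cctv(ct, label_mask(array(FALSE, c(10, 10, 10)))),
               "degenerate")
})

test_that("cCTv equals the brute-force per-voxel oracle on random phantoms", {
  set.seed(33)
  for (i in 1:10) {
    ph <- make_ct_phantom(phantom_spec(
      grid_shape = c(20L, 20L, 20L), cavity_radius_mm = 6,
      cortical_thickness_mm = 2,
      infiltration_fraction = runif(1), noise_sd_hu = runif(1, 0, 40),
      seed = i))
    wm <- medullary_working_mask(ph$ct, ph$masks$medullary_cavity,
                                 ph$masks$epiphysis)
    expect_equal(compute_cctv(ph$ct, wm)$cctv, oracle_cctv(ph$ct, wm),
                 tolerance = 1e-9)
  }
})

test_that("cCTv is monotone in infiltration fraction and lesion HU and
           recovers mu * f on noise-free constant phantoms", {
  cctv_of <- function(f, mu) {
    ph <- make_ct_phantom(phantom_spec(
      grid_shape = c(24L, 24L, 24L), cavity_radius_mm = 7,
      cortical_thickness_mm = 2, infiltration_fraction = f,
      lesion_hu_mean = mu, lesion_hu_sd = 0, fat_hu_sd = 0,
      noise_sd_hu = 0, seed = 9))
    list(cctv = compute_cctv(
      ph$ct, medullary_working_mask(ph$ct, ph$masks$medullary_cavity,
                                    ph$masks$epiphysis))$cctv,
      f_real = ph$truth$infiltration_fraction)
  }
  v1 <- cctv_of(0.1, 40); v2 <- cctv_of(0.3, 40); v3 <- cctv_of(0.6, 40)
  expect_true(v1$cctv <= v2$cctv && v2$cctv <= v3$cctv)
  w1 <- cctv_of(0.3, 20); w2 <- cctv_of(0.3, 60)
  expect_lte(w1$cctv, w2$cctv)
  # exact recovery: cCTv = mu * realized f
  expect_equal(v2$cctv, 40 * v2$f_real, tolerance = 1e-12)
})
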