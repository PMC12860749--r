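noise_free_spec <- function(..., noise_sd_hu = 0) {
  phantom_spec(grid_shape = c(32L, 32L, 32L), noise_sd_hu = noise_sd_hu,
               cavity_radius_mm = 9, cortical_thickness_mm = 3, ...)
}

test_that("phantom generation is deterministic under spec + seed", {
  sp <- noise_free_spec(infiltration_fraction = 0.3, noise_sd_hu = 5,
                        seed = 99)
  a <- make_ct_phantom(sp)
  b <- make_ct_phantom(sp)
  expect_identical(a$ct$data, b$ct$data)
  expect_identical(a$masks$mm$data, b$masks$mm$data)
  expect_identical(a$truth, b$truth)
  c_ <- make_ct_phantom(noise_free_spec(infiltration_fraction = 0.3,
                                        noise_sd_hu = 5, seed = 100))
  expect_false(identical(a$ct$data, c_$ct$data))
})

test_that("noise-free tissue values respect the declared HU bands", {
  for (f in c(0, 0.4)) {
    ph <- make_ct_phantom(noise_free_spec(infiltration_fraction = f,
                                          seed = 5))
    cav_hu <- ph$ct$data[ph$masks$medullary_cavity$data]
    inf_hu <- ph$ct$data[ph$masks$mm$data]
    fat_hu <- ph$ct$data[ph$masks$medullary_cavity$data &
                           !ph$masks$mm$data]
    expect_true(all(fat_hu >= -200 & fat_hu <= -30))
    if (f > 0) expect_true(all(inf_hu > -30 & inf_hu <= 120))
    if (f == 0) expect_true(all(cav_hu >= -200 & cav_hu <= -30))
    cort_hu <- ph$ct$data[ph$masks$cortical$data]
    expect_true(all(cort_hu > 120))
  }
})

test_that("realized infiltrated fraction matches the requested fraction", {
  for (pattern in c("diffuse", "focal", "mixed")) {
    sp <- noise_free_spec(infiltration_fraction = 0.25,
                          infiltration_pattern = pattern,
                          n_focal_lesions = 3L, seed = 17)
    ph <- make_ct_phantom(sp)
    n_cav <- sum(ph$masks$medullary_cavity$data)
    realized <- sum(ph$ct$data[ph$masks$medullary_cavity$data] > -30) /
      n_cav
    # exact-count sampling: realized fraction = round(f*N)/N
    expect_equal(realized, round(0.25 * n_cav) / n_cav, tolerance = 1e-12)
    expect_lt(abs(realized - 0.25), 1 / sqrt(n_cav))
    expect_equal(ph$truth$infiltration_fraction, realized)
  }
})

test_that("cortical, cavity and epiphysis masks are pairwise disjoint and
           the epiphysis covers the stated end fraction", {
  sp <- noise_free_spec(epiphysis_fraction = 0.2, seed = 3)
  ph <- make_ct_phantom(sp)
  m <- ph$masks
  expect_false(any(m$medullary_cavity$data & m$cortical$data))
  expect_false(any(m$medullary_cavity$data & m$epiphysis$data))
  expect_false(any(m$cortical$data & m$epiphysis$data))
  # epiphysis slices: floor(0.2 * 32) = 6 at each end of the bone axis
  z_any <- apply(m$epiphysis$data, 3, any)
  expect_identical(which(z_any), c(1:6, 27:32))
  z_cav <- apply(m$medullary_cavity$data, 3, any)
  expect_identical(which(z_cav), 7:26)
})

test_that("invalid phantom specs are rejected", {
  expect_error(phantom_spec(infiltration_fraction = 1.2), "\\[0, 1\\]")
  expect_error(phantom_spec(epiphysis_fraction = 0.5), "0.5")
  expect_error(phantom_spec(cortical_hu = 100), "exceed 120")
  expect_error(phantom_spec(fat_hu_mean = -250), "-200")
  expect_error(phantom_spec(lesion_hu_mean = 150), "120")
  # shell + cavity must fit in the cross-section
  expect_error(phantom_spec(grid_shape = c(16L, 16L, 32L),
                            cavity_radius_mm = 12,
                            cortical_thickness_mm = 4), "too small")
})

test_that("PET phantom honors reference means and the marrow uptake model", {
  ph <- make_ct_phantom(noise_free_spec(infiltration_fraction = 0, seed = 2))
  ps <- pet_spec(marrow_suv_slope = 0, noise_sd_suv = 0, background_suv = 0.7,
                 liver_suv_mean = 2.0, liver_suv_sd = 0, seed = 2)
  pp <- make_pet_phantom(ps, ph$masks, ph$truth)
  marrow <- voi_stats(pp$pet, ph$masks$medullary_cavity)
  expect_identical(marrow$suv_mean, 0.7)
  liver <- voi_stats(pp$pet, pp$masks$liver)
  expect_identical(liver$suv_median, 2.0)
  medi <- voi_stats(pp$pet, pp$masks$mediastinum)
  expect_identical(medi$suv_mean, 1.5)

  # monotone uptake in infiltration (slope > 0, zero noise)
  mean_marrow <- function(f) {
    ct <- make_ct_phantom(noise_free_spec(infiltration_fraction = f,
                                          seed = 8))
    pet <- make_pet_phantom(pet_spec(noise_sd_suv = 0, seed = 8), ct$masks,
                            ct$truth)
    voi_stats(pet$pet, ct$masks$medullary_cavity)$suv_mean
  }
  expect_lt(mean_marrow(0.1), mean_marrow(0.4))
})

test_that("PET reference masks are disjoint from each other and the bone", {
  ph <- make_ct_phantom(noise_free_spec(seed = 4))
  pp <- make_pet_phantom(pet_spec(seed = 4), ph$masks, ph$truth)
  m <- pp$masks
  expect_false(any(m$liver$data & m$mediastinum$data))
  expect_false(any(m$liver$data & m$skeleton$data))
  expect_false(any(m$mediastinum$data & m$skeleton$data))
  expect_true(all(m$skull$data | !m$skull$data))  # well-formed
  expect_true(any(m$skull$data))
  expect_true(all(m$skeleton$data[m$skull$data]))
})

test_that("cohort generation: structure, pairing and treatment effect", {
  cs <- small_cohort_spec(n_patients = 10L, treatment_effect = 0,
                          seed = 31)
  co <- make_cohort(cs)
  expect_equal(nrow(co$truth), 20L)
  base <- co$truth[co$truth$timepoint == "baseline", ]
  fu <- co$truth[co$truth$timepoint == "followup", ]
  expect_equal(fu$true_infiltration[order(fu$patient)],
               base$true_infiltration[order(base$patient)])

  cs2 <- small_cohort_spec(n_patients = 10L, treatment_effect = 0.8,
                           seed = 31)
  co2 <- make_cohort(cs2)
  fu2 <- co2$truth[co2$truth$timepoint == "followup", ]
  base2 <- co2$truth[co2$truth$timepoint == "baseline", ]
  expect_equal(fu2$true_infiltration[order(fu2$patient)],
               base2$true_infiltration[order(base2$patient)] * 0.2)
})

test_that("noise-free covariate links are perfectly monotone", {
  cs <- small_cohort_spec(n_patients = 15L, plasma_noise_sd = 0,
                          b2m_noise_sd = 0, seed = 7)
  co <- make_cohort(cs)
  base <- co$truth[co$truth$timepoint == "baseline", ]
  expect_equal(spearman(base$true_infiltration, base$plasma_pct)$estimate,
               1.0)
  expect_equal(spearman(base$true_infiltration, base$beta2m_mg_l)$estimate,
               1.0)
})

test_that("cohorts are reproducible and realize deterministically", {
  cs <- small_cohort_spec(n_patients = 4L, seed = 12)
  a <- make_cohort(cs); b <- make_cohort(cs)
  expect_identical(a$truth, b$truth)
  s1 <- realize_patient(a, 2, "baseline")
  s2 <- realize_patient(b, 2, "baseline")
  expect_identical(s1$ct$data, s2$ct$data)
  expect_identical(s1$pet$data, s2$pet$data)
  expect_error(realize_patient(a, 99, "baseline"), "no cohort row")
})
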