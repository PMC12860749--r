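# Fixture builders: everything is generated in code at test time.

# a uniform CT cylinder phantom built directly (bypassing make_ct_phantom)
# so that CT-module tests do not depend on the generator under test
fixture_cylinder_ct <- function(shape = c(24L, 24L, 24L), spacing = c(1, 1, 1),
                                cavity_hu = -80, radius_mm = 8) {
  idx <- arrayInd(seq_len(prod(shape)), shape)
  cx <- (shape[1] - 1) / 2; cy <- (shape[2] - 1) / 2
  r <- sqrt(((idx[, 1] - 1 - cx) * spacing[1])^2 +
              ((idx[, 2] - 1 - cy) * spacing[2])^2)
  cavity <- array(r <= radius_mm, shape)
  hu <- array(0, shape)
  hu[cavity] <- cavity_hu
  list(ct = volume_grid(hu, spacing = spacing, units = "HU"),
       cavity = label_mask(cavity, spacing = spacing,
                           label = "medullary_cavity"),
       empty = label_mask(array(FALSE, shape), spacing = spacing,
                          label = "epiphysis"))
}

# paint a solid sphere of `value` into a volume, in-place on a copy
paint_sphere <- function(vol, center_vox, radius_mm, value) {
  shp <- dim(vol$data)
  idx <- arrayInd(seq_len(prod(shp)), shp)
  d2 <- ((idx[, 1] - center_vox[1]) * vol$spacing[1])^2 +
    ((idx[, 2] - center_vox[2]) * vol$spacing[2])^2 +
    ((idx[, 3] - center_vox[3]) * vol$spacing[3])^2
  vol$data[d2 <= radius_mm^2] <- value
  vol
}

random_volume <- function(shape = c(8L, 8L, 8L), spacing = c(1, 1, 1),
                          lo = 0, hi = 5) {
  volume_grid(array(stats::runif(prod(shape), lo, hi), shape),
              spacing = spacing)
}

random_mask <- function(shape = c(8L, 8L, 8L), spacing = c(1, 1, 1),
                        p = 0.5) {
  m <- array(stats::runif(prod(shape)) < p, shape)
  if (!any(m)) m[1] <- TRUE
  label_mask(m, spacing = spacing, label = "random")
}

# small cohort spec used by simulation tests: coarse grid keeps each
# realized phantom cheap while preserving every pipeline stage
small_cohort_spec <- function(n_patients = 40L, seed = 1L, ...) {
  ct <- phantom_spec(grid_shape = c(24L, 24L, 40L),
                     voxel_spacing = c(2, 2, 2),
                     cavity_radius_mm = 12, cortical_thickness_mm = 4,
                     noise_sd_hu = 10)
  cohort_spec(n_patients = n_patients, ct_template = ct, seed = seed, ...)
}
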