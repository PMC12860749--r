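#' Synthetic long-bone CT phantom specification
#'
#' Describes an idealized long bone: a cylindrical cortical shell along
#' `bone_axis` enclosing a medullary cavity filled with fatty marrow, a
#' configurable fraction of which is replaced by myelomatous infiltration.
#' HU defaults follow the standard appendicular-marrow bands: fatty marrow
#' in [-200, -30] HU, infiltrated marrow in (-30, 120] HU, cortical bone
#' above 120 HU. Epiphyses occupy a stated fraction of bone length at each
#' end (their boundary is not anatomically defined; the end-fraction is a
#' modelling choice).
#'
#' @param grid_shape Integer length-3, voxel counts per axis.
#' @param voxel_spacing Numeric length-3, mm.
#' @param bone_axis Axis index (1-3) of the diaphysis; default 3.
#' @param cavity_radius_mm,cortical_thickness_mm Cylinder geometry, mm.
#' @param cortical_hu Shell HU, must exceed 120.
#' @param fat_hu_mean,fat_hu_sd Fatty-marrow HU distribution (values are
#'   clamped to the fat band so that noise-free phantoms are band-compliant).
#' @param lesion_hu_mean,lesion_hu_sd Infiltrated-marrow HU distribution
#'   (clamped to the infiltrated band).
#' @param infiltration_fraction Fraction of cavity voxels infiltrated, in
#'   [0, 1]. Realized as exactly `round(f * N_cavity)` voxels so that
#'   noise-free recovery is exact.
#' @param infiltration_pattern "diffuse" (scattered voxels), "focal"
#'   (spherical lesions grown from `n_focal_lesions` seeds), or "mixed"
#'   (half the target fraction each).
#' @param n_focal_lesions Number of focal seeds for focal/mixed patterns.
#' @param epiphysis_fraction Fraction of bone length per end in [0, 0.5).
#' @param noise_sd_hu Additive Gaussian CT noise, HU.
#' @param seed Integer RNG seed; fully determines the phantom.
#' @return A validated `phantom_spec` list.
#' @export
phantom_spec <- function(grid_shape = c(64L, 64L, 64L),
                         voxel_spacing = c(1, 1, 1),
                         bone_axis = 3L,
                         cavity_radius_mm = 12,
                         cortical_thickness_mm = 4,
                         cortical_hu = 1000,
                         fat_hu_mean = -100, fat_hu_sd = 15,
                         lesion_hu_mean = 40, lesion_hu_sd = 15,
                         infiltration_fraction = 0.3,
                         infiltration_pattern = c("diffuse", "focal", "mixed"),
                         n_focal_lesions = 3L,
                         epiphysis_fraction = 0.15,
                         noise_sd_hu = 0,
                         seed = 1L) {
  infiltration_pattern <- match.arg(infiltration_pattern)
  spec <- list(grid_shape = as.integer(grid_shape),
               voxel_spacing = as.numeric(voxel_spacing),
               bone_axis = as.integer(bone_axis),
               cavity_radius_mm = cavity_radius_mm,
               cortical_thickness_mm = cortical_thickness_mm,
               cortical_hu = cortical_hu,
               fat_hu_mean = fat_hu_mean, fat_hu_sd = fat_hu_sd,
               lesion_hu_mean = lesion_hu_mean, lesion_hu_sd = lesion_hu_sd,
               infiltration_fraction = infiltration_fraction,
               infiltration_pattern = infiltration_pattern,
               n_focal_lesions = as.integer(n_focal_lesions),
               epiphysis_fraction = epiphysis_fraction,
               noise_sd_hu = noise_sd_hu,
               seed = as.integer(seed))
  class(spec) <- "phantom_spec"
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(spec) {
  stop_spec <- function(msg) stop("invalid phantom spec: ", msg,
                                  call. = FALSE)
  if (length(spec$grid_shape) != 3L || any(spec$grid_shape < 4L))
    stop_spec("grid_shape must be 3 counts >= 4")
  if (any(spec$voxel_spacing <= 0)) stop_spec("voxel_spacing must be > 0")
  if (!spec$bone_axis %in% 1:3) stop_spec("bone_axis must be 1, 2 or 3")
  if (spec$infiltration_fraction < 0 || spec$infiltration_fraction > 1)
    stop_spec("infiltration_fraction must be in [0, 1]")
  if (spec$epiphysis_fraction < 0 || spec$epiphysis_fraction >= 0.5)
    stop_spec("epiphysis_fraction must be in [0, 0.5)")
  if (spec$cortical_hu <= 120) stop_spec("cortical_hu must exceed 120")
  if (spec$fat_hu_mean < -200 || spec$fat_hu_mean > -30)
    stop_spec("fat_hu_mean must lie in [-200, -30]")
  if (spec$lesion_hu_mean <= -30 || spec$lesion_hu_mean > 120)
    stop_spec("lesion_hu_mean must lie in (-30, 120]")
  if (spec$cavity_radius_mm <= 0 || spec$cortical_thickness_mm <= 0)
    stop_spec("cylinder radii must be positive")
  if (spec$noise_sd_hu < 0 || spec$fat_hu_sd < 0 || spec$lesion_hu_sd < 0)
    stop_spec("sd parameters must be >= 0")
  if (spec$infiltration_pattern != "diffuse" && spec$n_focal_lesions < 1L)
    stop_spec("n_focal_lesions must be >= 1 for focal/mixed patterns")
  # the shell plus cavity must fit inside the cross-section
  cross <- setdiff(1:3, spec$bone_axis)
  half_extent <- min((spec$grid_shape[cross] - 1) / 2 *
                       spec$voxel_spacing[cross])
  if (spec$cavity_radius_mm + spec$cortical_thickness_mm >= half_extent)
    stop_spec(sprintf(
      "grid too small: outer radius %.1f mm >= half cross-section %.1f mm",
      spec$cavity_radius_mm + spec$cortical_thickness_mm, half_extent))
  invisible(spec)
}

# run expr under a temporary RNG state seeded with `seed`
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Generate a synthetic long-bone CT phantom
#'
#' Builds the cylindrical bone described by a [phantom_spec()]: soft tissue
#' (0 HU) outside the bone, a cortical shell at `cortical_hu`, epiphyseal
#' segments at both ends (80 HU trabecular surrogate) and a medullary cavity
#' of fatty marrow with exactly `round(f * N_cavity)` voxels replaced by
#' infiltrated-band HU values. Identical spec and seed give bitwise-identical
#' output.
#'
#' @param spec A [phantom_spec()].
#' @return A list with elements `ct` ([volume_grid()], HU), `masks` (list of
#'   [label_mask()]: `medullary_cavity`, `epiphysis`, `cortical`, plus the
#'   ground-truth `mm` infiltration mask and `focal` lesion mask), and
#'   `truth` (realized infiltration fraction, mean lesion HU, MM and cavity
#'   volumes in mm^3, focal lesion count).
#' @export
make_ct_phantom <- function(spec) {
  validate_phantom_spec(spec)
  shp <- spec$grid_shape
  sp <- spec$voxel_spacing
  ax <- spec$bone_axis
  cross <- setdiff(1:3, ax)

  # radial distance of every voxel from the bone axis, in mm
  cc <- lapply(1:3, function(a) ((seq_len(shp[a]) - 1) -
                                   (shp[a] - 1) / 2) * sp[a])
  idx <- arrayInd(seq_len(prod(shp)), .dim = shp)
  r2 <- (cc[[cross[1]]][idx[, cross[1]]])^2 +
    (cc[[cross[2]]][idx[, cross[2]]])^2
  r <- sqrt(r2)
  along <- idx[, ax]

  n_axis <- shp[ax]
  n_epi <- floor(spec$epiphysis_fraction * n_axis)
  is_end <- along <= n_epi | along > n_axis - n_epi

  r_cav <- spec$cavity_radius_mm
  r_out <- r_cav + spec$cortical_thickness_mm
  in_bone <- r <= r_out
  epiphysis <- in_bone & is_end
  cortical <- in_bone & !is_end & r > r_cav
  cavity <- in_bone & !is_end & r <= r_cav
  n_cav <- sum(cavity)
  if (n_cav == 0L)
    stop("invalid phantom spec: cavity contains no voxels", call. = FALSE)

  out <- with_seed(spec$seed, {
    hu <- numeric(prod(shp))                       # soft tissue at 0 HU
    hu[epiphysis] <- 80
    hu[cortical] <- spec$cortical_hu
    fat <- clamp(stats::rnorm(n_cav, spec$fat_hu_mean, spec$fat_hu_sd),
                 -200, -30)
    hu[cavity] <- fat

    k <- round(spec$infiltration_fraction * n_cav)
    cav_idx <- which(cavity)
    inf_idx <- integer(0)
    focal_idx <- integer(0)
    if (k > 0L) {
      pick_focal <- function(target, exclude) {
        # grow spherical lesions around random cavity seeds until `target`
        # voxels are covered: rank cavity voxels by distance to the nearest
        # seed and take the closest `target`
        pool <- setdiff(cav_idx, exclude)
        seeds <- sample(pool, min(spec$n_focal_lesions, length(pool)))
        pi <- idx[pool, , drop = FALSE]
        si <- idx[seeds, , drop = FALSE]
        dmin <- rep(Inf, length(pool))
        for (s in seq_len(nrow(si))) {
          ds <- ((pi[, 1] - si[s, 1]) * sp[1])^2 +
            ((pi[, 2] - si[s, 2]) * sp[2])^2 +
            ((pi[, 3] - si[s, 3]) * sp[3])^2
          dmin <- pmin(dmin, ds)
        }
        pool[order(dmin, pool)[seq_len(min(target, length(pool)))]]
      }
      if (spec$infiltration_pattern == "diffuse") {
        inf_idx <- sample(cav_idx, k)
      } else if (spec$infiltration_pattern == "focal") {
        focal_idx <- pick_focal(k, integer(0))
        inf_idx <- focal_idx
      } else {                                     # mixed
        k_focal <- floor(k / 2)
        focal_idx <- pick_focal(k_focal, integer(0))
        rest <- setdiff(cav_idx, focal_idx)
        inf_idx <- c(focal_idx, sample(rest, k - length(focal_idx)))
      }
      lesion_hu <- clamp(stats::rnorm(length(inf_idx), spec$lesion_hu_mean,
                                      spec$lesion_hu_sd),
                         -30 + 1e-9, 120)
      hu[inf_idx] <- lesion_hu
    }
    mean_lesion_hu <- if (length(inf_idx)) mean(hu[inf_idx]) else NA_real_
    if (spec$noise_sd_hu > 0)
      hu <- hu + stats::rnorm(length(hu), 0, spec$noise_sd_hu)
    list(hu = hu, inf_idx = inf_idx, focal_idx = focal_idx,
         mean_lesion_hu = mean_lesion_hu)
  })

  to_mask <- function(sel, label) {
    m <- logical(prod(shp))
    m[sel] <- TRUE
    label_mask(array(m, shp), spacing = sp, label = label)
  }
  vx <- prod(sp)
  truth <- list(
    infiltration_fraction = length(out$inf_idx) / n_cav,
    target_infiltration_fraction = spec$infiltration_fraction,
    mean_lesion_hu = out$mean_lesion_hu,
    mm_volume_mm3 = length(out$inf_idx) * vx,
    cavity_volume_mm3 = n_cav * vx,
    n_focal_lesions = if (length(out$focal_idx))
      spec$n_focal_lesions else 0L)

  list(ct = volume_grid(array(out$hu, shp), spacing = sp, units = "HU"),
       masks = list(medullary_cavity = to_mask(which(cavity),
                                               "medullary_cavity"),
                    epiphysis = to_mask(which(epiphysis), "epiphysis"),
                    cortical = to_mask(which(cortical), "cortical"),
                    mm = to_mask(out$inf_idx, "mm"),
                    focal = to_mask(out$focal_idx, "focal_lesion")),
       truth = truth)
}

#' Synthetic PET phantom specification
#'
#' Uptake model for the PET half of a phantom pair: uniform soft-tissue
#' background, reference organs (liver, mediastinal blood pool) placed as
#' rectangular VOIs away from the bone, a high-uptake skull sphere standing
#' in for physiological brain activity, and marrow uptake that increases
#' linearly with local infiltration:
#' `SUV = background + marrow_suv_slope * 1(infiltrated) + noise`.
#'
#' @param injected_dose_MBq_per_kg Acquisition metadata; default 3.
#' @param body_weight_kg Metadata; default 75.
#' @param background_suv Normal-marrow / soft-tissue SUV.
#' @param mediastinum_suv Mediastinal blood-pool SUV (constant).
#' @param liver_suv_mean,liver_suv_sd Liver SUV distribution.
#' @param marrow_suv_slope Gain from infiltration indicator to marrow SUV.
#' @param focal_lesion_suv SUV assigned to focal-lesion voxels (overrides the
#'   linear model there); 0 disables.
#' @param skull_suv Skull/brain surrogate SUV.
#' @param noise_sd_suv Additive Gaussian SUV noise (clamped at 0).
#' @param seed Integer RNG seed.
#' @return A validated `pet_spec` list.
#' @export
pet_spec <- function(injected_dose_MBq_per_kg = 3,
                     body_weight_kg = 75,
                     background_suv = 0.8,
                     mediastinum_suv = 1.5,
                     liver_suv_mean = 2.3, liver_suv_sd = 0.2,
                     marrow_suv_slope = 5,
                     focal_lesion_suv = 0,
                     skull_suv = 8,
                     noise_sd_suv = 0,
                     seed = 1L) {
  spec <- list(injected_dose_MBq_per_kg = injected_dose_MBq_per_kg,
               body_weight_kg = body_weight_kg,
               background_suv = background_suv,
               mediastinum_suv = mediastinum_suv,
               liver_suv_mean = liver_suv_mean, liver_suv_sd = liver_suv_sd,
               marrow_suv_slope = marrow_suv_slope,
               focal_lesion_suv = focal_lesion_suv,
               skull_suv = skull_suv,
               noise_sd_suv = noise_sd_suv,
               seed = as.integer(seed))
  class(spec) <- "pet_spec"
  num <- vapply(spec[setdiff(names(spec), "seed")], identity, numeric(1))
  if (any(!is.finite(num)) || any(num < 0))
    stop("invalid PET spec: all SUV/dose parameters must be >= 0",
         call. = FALSE)
  if (spec$injected_dose_MBq_per_kg <= 0 || spec$body_weight_kg <= 0)
    stop("invalid PET spec: dose and weight must be positive", call. = FALSE)
  spec
}

# corner box mask helper: fractions of each axis extent
corner_box <- function(shp, fr) {
  sel <- lapply(1:3, function(a) {
    lo <- max(1L, ceiling(fr[[a]][1] * shp[a]))
    hi <- min(shp[a], floor(fr[[a]][2] * shp[a]))
    seq(lo, hi)
  })
  m <- array(FALSE, shp)
  m[sel[[1]], sel[[2]], sel[[3]]] <- TRUE
  m
}

#' Generate the PET half of a phantom pair
#'
#' @param spec A [pet_spec()].
#' @param ct_masks Mask list from [make_ct_phantom()] (needs
#'   `medullary_cavity`, `epiphysis`, `cortical`, `mm`, `focal`).
#' @param truth Ground-truth list from [make_ct_phantom()] (unused by the
#'   uptake model itself but carried through for provenance).
#' @return List with `pet` ([volume_grid()], SUV) and `masks`
#'   (`skeleton`, `skull`, `liver`, `mediastinum`, `lesions`).
#' @export
make_pet_phantom <- function(spec, ct_masks, truth = NULL) {
  cav <- ct_masks$medullary_cavity
  for (m in ct_masks) assert_aligned(cav, m, "CT masks")
  shp <- dim(cav$data)
  sp <- cav$spacing

  # reference organs in opposite low-x corners, clear of the central bone
  liver_m <- corner_box(shp, list(c(0.02, 0.18), c(0.02, 0.18),
                                  c(0.30, 0.60)))
  medi_m <- corner_box(shp, list(c(0.82, 0.98), c(0.02, 0.18),
                                 c(0.30, 0.60)))
  skull_m <- corner_box(shp, list(c(0.82, 0.98), c(0.82, 0.98),
                                  c(0.82, 0.95)))
  bone <- cav$data | ct_masks$epiphysis$data | ct_masks$cortical$data
  if (any(liver_m & medi_m) || any(liver_m & bone) || any(medi_m & bone) ||
      any(skull_m & (liver_m | medi_m | bone)))
    stop("invalid PET spec: reference-organ masks overlap", call. = FALSE)

  suv <- with_seed(spec$seed, {
    v <- rep(spec$background_suv, prod(shp))
    v[which(liver_m)] <- clamp(
      stats::rnorm(sum(liver_m), spec$liver_suv_mean, spec$liver_suv_sd),
      0, Inf)
    v[which(medi_m)] <- spec$mediastinum_suv
    v[which(skull_m)] <- spec$skull_suv
    # marrow: background + slope * infiltration indicator
    inf_idx <- which(ct_masks$mm$data)
    v[inf_idx] <- spec$background_suv + spec$marrow_suv_slope
    if (spec$focal_lesion_suv > 0) {
      v[which(ct_masks$focal$data)] <- spec$focal_lesion_suv
    }
    if (spec$noise_sd_suv > 0)
      v <- clamp(v + stats::rnorm(length(v), 0, spec$noise_sd_suv), 0, Inf)
    v
  })

  mk <- function(m, label) label_mask(array(m, shp), spacing = sp,
                                      label = label)
  skel <- bone | skull_m
  list(pet = volume_grid(array(suv, shp), spacing = sp, units = "SUV"),
       masks = list(skeleton = mk(skel, "skeleton"),
                    skull = mk(skull_m, "skull"),
                    liver = mk(liver_m, "liver"),
                    mediastinum = mk(medi_m, "mediastinum"),
                    lesions = mk(ct_masks$focal$data, "lesions")))
}
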