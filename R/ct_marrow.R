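#' Hounsfield-unit tissue classification for appendicular marrow
#'
#' Partitions every finite HU value into one of four classes using the
#' standard appendicular bands: fatty marrow in \[-200, -30\] HU, myelomatous
#' (infiltrated) marrow in (-30, 120\] HU, cortical bone above 120 HU, and
#' out_of_range below -200 HU. Band boundaries are half-open so the four
#' classes form a partition of the finite reals.
#'
#' @param hu Numeric vector of HU values (finite).
#' @return Factor with levels `fat_marrow`, `infiltrated`, `cortical`,
#'   `out_of_range`, same length as `hu`.
#' @export
classify_voxel <- function(hu) {
  if (!is.numeric(hu) || any(!is.finite(hu)))
    stop("HU values must be finite numbers", call. = FALSE)
  cls <- character(length(hu))
  cls[hu < -200] <- "out_of_range"
  cls[hu >= -200 & hu <= -30] <- "fat_marrow"
  cls[hu > -30 & hu <= 120] <- "infiltrated"
  cls[hu > 120] <- "cortical"
  factor(cls, levels = c("fat_marrow", "infiltrated", "cortical",
                         "out_of_range"))
}

#' Medullary working mask for CT quantification
#'
#' The evaluation volume for both CT approaches: the medullary cavity with
#' epiphyses removed and any voxel brighter than cortical threshold
#' (HU > 120) excluded. A cavity voxel at exactly 120 HU is kept (the
#' cortical boundary is strict).
#'
#' @param ct CT [volume_grid()] in HU.
#' @param cavity Medullary-cavity [label_mask()].
#' @param epiphysis Epiphysis [label_mask()] (may be empty).
#' @return A [label_mask()] labelled "medullary_working".
#' @export
medullary_working_mask <- function(ct, cavity, epiphysis) {
  assert_aligned(ct, cavity, "CT and cavity mask")
  assert_aligned(ct, epiphysis, "CT and epiphysis mask")
  keep <- cavity$data & !epiphysis$data & !(ct$data > 120)
  label_mask(keep, spacing = ct$spacing, origin = ct$origin,
             label = "medullary_working")
}

# disc / ball offsets (in voxels) for a radius in mm; includes the center.
# disc offsets lie in the plane of `axes`; ball offsets span all three.
roi_offsets <- function(radius_mm, spacing, axes = c(1L, 2L),
                        shape = c("disc", "sphere")) {
  shape <- match.arg(shape)
  rng <- lapply(1:3, function(a) {
    if (shape == "disc" && !(a %in% axes)) return(0L)
    m <- floor(radius_mm / spacing[a])
    seq.int(-m, m)
  })
  off <- expand.grid(di = rng[[1]], dj = rng[[2]], dk = rng[[3]])
  d2 <- (off$di * spacing[1])^2 + (off$dj * spacing[2])^2 +
    (off$dk * spacing[3])^2
  off[d2 <= radius_mm^2 + 1e-9, , drop = FALSE]
}

# sum of `vals` over ROI offsets at every center, via shifted-array adds;
# returns list(sum, count) where count is the number of offsets whose voxel
# is inside the grid AND inside `mask`
roi_sweep <- function(vals, mask, offsets) {
  shp <- dim(vals)
  S <- array(0, shp)
  C <- array(0L, shp)
  vm <- vals * mask                      # zero outside mask
  for (o in seq_len(nrow(offsets))) {
    d <- as.integer(offsets[o, ])
    src <- lapply(1:3, function(a) {
      i <- seq_len(shp[a]) + d[a]
      i[i >= 1L & i <= shp[a]]
    })
    dst <- lapply(1:3, function(a) src[[a]] - d[a])
    S[dst[[1]], dst[[2]], dst[[3]]] <-
      S[dst[[1]], dst[[2]], dst[[3]]] + vm[src[[1]], src[[2]], src[[3]]]
    C[dst[[1]], dst[[2]], dst[[3]]] <-
      C[dst[[1]], dst[[2]], dst[[3]]] + mask[src[[1]], src[[2]],
                                             src[[3]]]
  }
  list(sum = S, count = C)
}

#' Manual CT value (CTv): maximizing ROI sweep
#'
#' Deterministic surrogate for reader-placed circular ROIs: sweeps disc
#' (axial, default) or spherical ROIs of each candidate radius over every
#' working-mask voxel, keeps only ROIs fully contained in the mask, and
#' returns the highest ROI-mean HU together with the winning center and
#' radius. Reported per patient, this upper-bounds what a reader placing
#' ROIs "according to the size of the high-density area" could record.
#' Ties are broken deterministically by lowest (z, y, x) center index, then
#' by smaller radius.
#'
#' @param ct CT [volume_grid()] in HU.
#' @param working_mask [label_mask()] from [medullary_working_mask()].
#' @param radii_mm Candidate ROI radii in mm (default 3:6).
#' @param roi_shape "disc" (axial, perpendicular to `axis`) or "sphere".
#' @param axis Bone axis for disc orientation (default 3).
#' @param stride Evaluate every `stride`-th center along each axis (1 = all).
#' @return A `ct_quant_result`: `ctv` (HU), `best_roi` (center index,
#'   radius, shape), `per_radius` data.frame of best mean per radius.
#' @export
manual_ctv <- function(ct, working_mask, radii_mm = c(3, 4, 5, 6),
                       roi_shape = c("disc", "sphere"), axis = 3L,
                       stride = 1L) {
  roi_shape <- match.arg(roi_shape)
  assert_aligned(ct, working_mask, "CT and working mask")
  if (!any(working_mask$data))
    stop("degenerate mask: working mask is empty", call. = FALSE)
  if (any(radii_mm <= 0)) stop("radii must be positive", call. = FALSE)
  plane_axes <- setdiff(1:3, axis)
  shp <- dim(ct$data)
  mask <- working_mask$data
  storage.mode(mask) <- "integer"

  stride_ok <- array(TRUE, shp)
  if (stride > 1L) {
    sel <- lapply(shp, function(n) seq(1L, n, by = stride))
    stride_ok[] <- FALSE
    stride_ok[sel[[1]], sel[[2]], sel[[3]]] <- TRUE
  }

  best <- NULL
  per_radius <- data.frame(radius_mm = radii_mm, best_mean_hu = NA_real_)
  for (ri in seq_along(radii_mm)) {
    off <- roi_offsets(radii_mm[ri], ct$spacing, axes = plane_axes,
                       shape = roi_shape)
    sw <- roi_sweep(ct$data, mask, off)
    valid <- sw$count == nrow(off) & stride_ok   # ROI fully inside mask
    if (!any(valid)) next
    means <- sw$sum[valid] / nrow(off)
    vidx <- which(valid)
    mx <- max(means)
    per_radius$best_mean_hu[ri] <- mx
    # tie-break: lowest (z, y, x) among the argmax centers
    cand <- vidx[means >= mx - 0 & means == mx]
    ci <- arrayInd(cand, shp)
    ord <- order(ci[, 3], ci[, 2], ci[, 1])
    center <- ci[ord[1], ]
    if (is.null(best) || mx > best$ctv + 1e-12) {
      best <- list(ctv = mx, center = center, radius_mm = radii_mm[ri])
    }
  }
  if (is.null(best))
    stop("degenerate mask: no ROI of any requested radius fits inside ",
         "the working mask", call. = FALSE)
  structure(list(ctv = best$ctv,
                 best_roi = list(center = best$center,
                                 radius_mm = best$radius_mm,
                                 shape = roi_shape, axis = axis),
                 per_radius = per_radius),
            class = "ct_quant_result")
}

#' @export
print.ct_quant_result <- function(x, ...) {
  cat(sprintf("CTv = %.2f HU (ROI r = %g mm %s at [%s])\n", x$ctv,
              x$best_roi$radius_mm, x$best_roi$shape,
              paste(x$best_roi$center, collapse = ",")))
  invisible(x)
}

#' Cumulative CT value (cCTv): semi-automated marrow burden
#'
#' Classifies every working-mask voxel by [classify_voxel()]; voxels in the
#' infiltrated band (-30, 120\] HU form the myeloma (MM) compartment. The
#' published formula — cumulative voxel HU x MM volume / cavity volume — is
#' dimensionally ambiguous; the default "density" interpretation is
#'
#'   cCTv (HU) = (sum of HU over MM voxels x voxel volume) / cavity volume
#'             = mean MM HU x (V_MM / V_cavity),
#'
#' which carries HU units and matches the magnitude reported for this
#' statistic (~5 HU medians). `interpretation = "literal"` instead returns
#' the raw HU-sum times the volume ratio (units HU x mm^3).
#'
#' @param ct CT [volume_grid()] in HU.
#' @param working_mask [label_mask()]; its volume is the cavity denominator.
#' @param interpretation "density" (default) or "literal".
#' @return A `cctv_result`: `cctv`, `cumulative_hu` (plain HU sum over MM
#'   voxels), `mm_volume_mm3`, `cavity_volume_mm3`, `n_mm_voxels`,
#'   `interpretation`.
#' @export
compute_cctv <- function(ct, working_mask,
                         interpretation = c("density", "literal")) {
  interpretation <- match.arg(interpretation)
  assert_aligned(ct, working_mask, "CT and working mask")
  n_cav <- sum(working_mask$data)
  if (n_cav == 0L)
    stop("degenerate mask: cavity volume is zero", call. = FALSE)
  vx <- voxel_volume_mm3(ct)
  hu <- ct$data[working_mask$data]
  mm <- hu > -30 & hu <= 120
  cum_hu <- sum(hu[mm])
  v_mm <- sum(mm) * vx
  v_cav <- n_cav * vx
  cctv <- if (interpretation == "density") cum_hu * vx / v_cav
          else cum_hu * v_mm / v_cav
  if (sum(mm) == 0L) cctv <- 0
  structure(list(cctv = cctv, cumulative_hu = cum_hu,
                 mm_volume_mm3 = v_mm, cavity_volume_mm3 = v_cav,
                 n_mm_voxels = sum(mm), interpretation = interpretation),
            class = "cctv_result")
}

#' @export
print.cctv_result <- function(x, ...) {
  cat(sprintf("cCTv = %.3f %s (MM %.0f / cavity %.0f mm^3, %s reading)\n",
              x$cctv, if (x$interpretation == "density") "HU" else "HU.mm^3",
              x$mm_volume_mm3, x$cavity_volume_mm3, x$interpretation))
  invisible(x)
}
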