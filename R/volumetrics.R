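#' Liver-derived SUV threshold for marrow segmentation
#'
#' The segmentation threshold of the automated whole-skeleton pipeline: the
#' median SUV of the liver VOI. Voxels at or above the threshold count as
#' positive (inclusion is closed at the threshold).
#'
#' @param liver_stats `suv_stats` of the liver VOI (see [voi_stats()]).
#' @return Scalar threshold SUV.
#' @export
mm_threshold <- function(liver_stats) {
  if (!inherits(liver_stats, "suv_stats"))
    stop("`liver_stats` must be suv_stats from a nonempty liver VOI",
         call. = FALSE)
  liver_stats$suv_median
}

# binary erosion by a ball of radius `radius_mm` (world units): a voxel
# survives iff every voxel within the ball is inside the mask
erode_mask <- function(mask, radius_mm) {
  if (radius_mm <= 0) return(mask)
  off <- roi_offsets(radius_mm, mask$spacing, shape = "sphere")
  m <- mask$data
  storage.mode(m) <- "integer"
  sw <- roi_sweep(m * 0 + 1, m, off)      # count in-mask voxels per ball
  keep <- sw$count == nrow(off)
  label_mask(keep & mask$data, spacing = mask$spacing, origin = mask$origin,
             label = mask$label)
}

#' Skeletal working mask for MTV/TLG
#'
#' Removes the skull from the skeleton mask (to avoid physiological brain
#' uptake) and then erodes the remainder by `erosion_mm` as a surrogate for
#' the spillover-reduction step of the automated pipeline (PET resolution
#' blurs adjacent-tissue activity into the bone mask; the exact published
#' mitigation is unspecified, so a configurable morphological erosion is
#' used). `erosion_mm = 0` disables erosion.
#'
#' @param skeleton,skull Aligned [label_mask()]s.
#' @param erosion_mm Ball-erosion radius in mm, default 2.
#' @return Eroded [label_mask()] labelled "skeletal_working".
#' @export
skeletal_working_mask <- function(skeleton, skull, erosion_mm = 2) {
  assert_aligned(skeleton, skull, "skeleton and skull masks")
  base <- label_mask(skeleton$data & !skull$data,
                     spacing = skeleton$spacing, origin = skeleton$origin,
                     label = "skeletal_working")
  out <- erode_mask(base, erosion_mm)
  if (any(base$data) && !any(out$data))
    stop(sprintf(
      "degenerate mask: erosion by %g mm removed every skeletal voxel",
      erosion_mm), call. = FALSE)
  out
}

#' Threshold segmentation, MTV and TLG
#'
#' Segments working-mask voxels with SUV at or above the threshold and
#' reports the metabolic tumor volume MTV (ml) and total lesion glycolysis
#' TLG = SUVmean x MTV (g) over the segmented voxels. An empty segmentation
#' yields MTV = TLG = 0.
#'
#' @param suv SUV [volume_grid()].
#' @param working_mask [label_mask()] from [skeletal_working_mask()].
#' @param threshold_suv Scalar threshold, typically [mm_threshold()].
#' @return A `volumetric_result`: `mtv_ml`, `tlg_g`, `suv_mean`,
#'   `threshold_suv`, `n_voxels`, and the segmentation [label_mask()] as
#'   `segmentation`.
#' @export
segment_and_quantify <- function(suv, working_mask, threshold_suv) {
  assert_aligned(suv, working_mask, "SUV volume and working mask")
  if (!any(working_mask$data))
    stop("degenerate mask: skeletal working mask is empty", call. = FALSE)
  if (!is.finite(threshold_suv))
    stop("threshold must be finite", call. = FALSE)
  seg <- working_mask$data & suv$data >= threshold_suv
  n <- sum(seg)
  mtv_ml <- n * voxel_volume_mm3(suv) / 1000
  mu <- if (n > 0L) mean(suv$data[seg]) else 0
  structure(list(mtv_ml = mtv_ml, tlg_g = mu * mtv_ml, suv_mean = mu,
                 threshold_suv = threshold_suv, n_voxels = n,
                 segmentation = label_mask(seg, spacing = suv$spacing,
                                           origin = suv$origin,
                                           label = "mm_segmentation")),
            class = "volumetric_result")
}

#' @export
print.volumetric_result <- function(x, ...) {
  cat(sprintf("MTV = %.2f ml  TLG = %.2f g  (threshold SUV %.3f, %d voxels)\n",
              x$mtv_ml, x$tlg_g, x$threshold_suv, x$n_voxels))
  invisible(x)
}
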