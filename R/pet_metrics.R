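#' Body-weight standardized uptake value
#'
#' Converts an activity-concentration volume to SUV using the body-weight
#' normalization: `SUV = C / (dose / weight)` with the concentration C in
#' kBq/ml, the injected dose in MBq and the weight in kg (1 MBq/kg of body
#' weight corresponds to 1 kBq/ml at SUV 1, taking 1 g/ml tissue density).
#' Decay correction is assumed to have been applied upstream.
#'
#' @param activity [volume_grid()] of activity concentration in kBq/ml.
#' @param injected_dose_MBq Injected activity, MBq (> 0).
#' @param body_weight_kg Patient weight, kg (> 0).
#' @return SUV [volume_grid()].
#' @export
compute_suv <- function(activity, injected_dose_MBq, body_weight_kg) {
  if (!is.finite(injected_dose_MBq) || injected_dose_MBq <= 0)
    stop("injected dose must be a positive number (MBq)", call. = FALSE)
  if (!is.finite(body_weight_kg) || body_weight_kg <= 0)
    stop("body weight must be a positive number (kg)", call. = FALSE)
  suv <- activity$data / (injected_dose_MBq / body_weight_kg)
  volume_grid(suv, spacing = activity$spacing, origin = activity$origin,
              units = "SUV")
}

#' SUV statistics over a volume of interest
#'
#' Exact max / mean / median over the masked voxels, plus voxel count and
#' VOI volume in ml.
#'
#' @param suv SUV [volume_grid()].
#' @param mask Nonempty [label_mask()] aligned to `suv`.
#' @return A `suv_stats` list: `suv_max`, `suv_mean`, `suv_median`,
#'   `voxel_count`, `volume_ml`.
#' @export
voi_stats <- function(suv, mask) {
  assert_aligned(suv, mask, "SUV volume and VOI mask")
  vals <- suv$data[mask$data]
  if (length(vals) == 0L)
    stop(sprintf("degenerate mask: VOI '%s' is empty", mask$label),
         call. = FALSE)
  structure(list(suv_max = max(vals), suv_mean = mean(vals),
                 suv_median = stats::median(vals),
                 voxel_count = length(vals),
                 volume_ml = length(vals) * voxel_volume_mm3(suv) / 1000),
            class = "suv_stats")
}

#' @export
print.suv_stats <- function(x, ...) {
  cat(sprintf(
    "SUVmax %.2f  SUVmean %.2f  SUVmedian %.2f  (%d voxels, %.2f ml)\n",
    x$suv_max, x$suv_mean, x$suv_median, x$voxel_count, x$volume_ml))
  invisible(x)
}

#' Nearest-neighbor mask resampling between grids
#'
#' Transfers a label mask onto a target voxel lattice by nearest-neighbor
#' lookup in world coordinates (labels are never interpolated). Target
#' voxels whose nearest source voxel center is more than half a source
#' voxel away on any axis fall outside the source field of view and are
#' left unset; a warning is raised if the mask lands entirely outside.
#' When the grids already coincide, the mask is returned unchanged.
#'
#' @param mask Source [label_mask()].
#' @param target [volume_grid()] (or mask) defining the output lattice.
#' @return A [label_mask()] on the target lattice.
#' @export
resample_mask <- function(mask, target) {
  if (identical(dim(mask$data), dim(target$data)) &&
      max(abs(mask$spacing - target$spacing)) <= 1e-9 &&
      max(abs(mask$origin - target$origin)) <= 1e-9)
    return(mask)

  src_dim <- dim(mask$data)
  tgt_dim <- dim(target$data)
  # nearest source index per target coordinate, per axis; NA outside FOV
  nn <- lapply(1:3, function(a) {
    w <- axis_coords(target, a)
    i <- round((w - mask$origin[a]) / mask$spacing[a]) + 1
    i[i < 1 | i > src_dim[a]] <- NA_integer_
    as.integer(i)
  })
  out <- array(FALSE, tgt_dim)
  ok1 <- which(!is.na(nn[[1]])); ok2 <- which(!is.na(nn[[2]]))
  ok3 <- which(!is.na(nn[[3]]))
  if (length(ok1) && length(ok2) && length(ok3))
    out[ok1, ok2, ok3] <- mask$data[nn[[1]][ok1], nn[[2]][ok2],
                                    nn[[3]][ok3]]
  if (any(mask$data) && !any(out))
    warning(sprintf("mask '%s' lies wholly outside the target field of view",
                    mask$label), call. = FALSE)
  label_mask(out, spacing = target$spacing, origin = target$origin,
             label = mask$label)
}
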