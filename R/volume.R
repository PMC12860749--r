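#' 3D scalar volume with voxel geometry
#'
#' A `volume_grid` wraps a 3D numeric array together with its voxel spacing
#' (mm per axis) and world-space origin (mm). It is the common container for
#' CT volumes in Hounsfield units and PET volumes in SUV or activity
#' concentration.
#'
#' @param data 3D numeric array.
#' @param spacing Numeric length-3, voxel edge lengths in mm (all > 0).
#' @param origin Numeric length-3, world coordinate of the center of voxel
#'   (1,1,1), in mm.
#' @param units Free-text unit tag ("HU", "SUV", "kBq/ml", ...).
#' @return An object of class `volume_grid`.
#' @export
volume_grid <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                        units = "") {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array", call. = FALSE)
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 positive finite numbers (mm)", call. = FALSE)
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("`origin` must be 3 finite numbers (mm)", call. = FALSE)
  structure(list(data = data, spacing = spacing, origin = origin,
                 units = units),
            class = "volume_grid")
}

#' @export
print.volume_grid <- function(x, ...) {
  cat(sprintf("<volume_grid> %s  dims %s  spacing %s mm  units '%s'\n",
              format(utils::object.size(x$data), units = "auto"),
              paste(dim(x$data), collapse = "x"),
              paste(format(x$spacing), collapse = "x"), x$units))
  invisible(x)
}

#' @export
dim.volume_grid <- function(x) dim(x$data)

#' Volume of one voxel in mm^3
#' @param x A `volume_grid` or `label_mask`.
#' @return Scalar voxel volume in mm^3.
#' @export
voxel_volume_mm3 <- function(x) prod(x$spacing)

#' Binary region mask aligned to a volume grid
#'
#' @param data 3D logical (or coercible) array of the same shape as the
#'   volume it annotates.
#' @param spacing,origin Geometry, as for [volume_grid()].
#' @param label Semantic label, e.g. "medullary_cavity", "liver".
#' @return An object of class `label_mask`.
#' @export
label_mask <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                       label = "") {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("mask `data` must be a 3D array", call. = FALSE)
  storage.mode(data) <- "logical"
  if (anyNA(data)) stop("mask contains NA", call. = FALSE)
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("`spacing` must be 3 positive numbers (mm)", call. = FALSE)
  structure(list(data = data, spacing = spacing, origin = origin,
                 label = label),
            class = "label_mask")
}

#' @export
print.label_mask <- function(x, ...) {
  cat(sprintf("<label_mask '%s'> dims %s  %d voxels set (%.3g ml)\n",
              x$label, paste(dim(x$data), collapse = "x"),
              sum(x$data), mask_volume_mm3(x) / 1000))
  invisible(x)
}

#' @export
dim.label_mask <- function(x) dim(x$data)

#' Total mask volume in mm^3
#' @param mask A `label_mask`.
#' @export
mask_volume_mm3 <- function(mask) sum(mask$data) * voxel_volume_mm3(mask)

#' Check that two grids/masks share a voxel lattice
#'
#' Errors unless shapes, spacings and origins agree. Used as the alignment
#' precondition by every masked reduction.
#'
#' @param a,b `volume_grid` or `label_mask` objects.
#' @param what Context string for the error message.
#' @return Invisibly `TRUE`.
#' @export
assert_aligned <- function(a, b, what = "inputs") {
  if (!identical(dim(a$data), dim(b$data)))
    stop(sprintf("%s are not aligned: shapes %s vs %s", what,
                 paste(dim(a$data), collapse = "x"),
                 paste(dim(b$data), collapse = "x")), call. = FALSE)
  if (max(abs(a$spacing - b$spacing)) > 1e-6 ||
      max(abs(a$origin - b$origin)) > 1e-6)
    stop(sprintf("%s are not aligned: spacing/origin differ", what),
         call. = FALSE)
  invisible(TRUE)
}

# world coordinates (mm) of voxel centers along one axis
axis_coords <- function(x, axis) {
  x$origin[axis] + (seq_len(dim(x$data)[axis]) - 1) * x$spacing[axis]
}
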