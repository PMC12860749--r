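#' Read and write single-file NIfTI-1 volumes
#'
#' Minimal NIfTI-1 (.nii / .nii.gz) support sufficient for scalar volumes and
#' integer label maps: 3D data, little- or big-endian, datatypes uint8/int8,
#' int16/uint16, int32, float32 and float64, scl_slope/scl_inter rescaling,
#' voxel spacing from pixdim and origin from the sform (or qoffset)
#' translation. Orientation is taken as axis-aligned; oblique affines are not
#' interpreted.
#'
#' @param path File path; ".gz" suffixed files are transparently compressed.
#' @param units Unit tag stored on the returned [volume_grid()].
#' @return `read_volume`: a [volume_grid()]. `read_mask`: a [label_mask()]
#'   (nonzero voxels set).
#' @export
read_volume <- function(path, units = "") {
  if (!file.exists(path))
    stop(sprintf("file not found: %s", path), call. = FALSE)
  con <- gzfile(path, "rb")
  on.exit(close(con))
  raw_hdr <- readBin(con, "raw", n = 348L)
  if (length(raw_hdr) < 348L)
    stop(sprintf("not a NIfTI-1 file (truncated header): %s", path),
         call. = FALSE)
  endian <- "little"
  sizeof_hdr <- readBin(raw_hdr[1:4], "integer", size = 4, endian = endian)
  if (sizeof_hdr != 348L) {
    endian <- "big"
    sizeof_hdr <- readBin(raw_hdr[1:4], "integer", size = 4, endian = endian)
  }
  magic <- rawToChar(raw_hdr[345:347])
  if (sizeof_hdr != 348L || !(magic %in% c("n+1", "ni1")))
    stop(sprintf("not a NIfTI-1 file: %s", path), call. = FALSE)
  if (magic == "ni1")
    stop(sprintf("two-file (.hdr/.img) NIfTI not supported: %s", path),
         call. = FALSE)

  rd <- function(bytes, what, size, n = 1L, signed = TRUE)
    readBin(bytes, what, n = n, size = size, signed = signed, endian = endian)
  dims <- rd(raw_hdr[41:56], "integer", 2, n = 8)
  ndim <- dims[1]
  if (ndim < 1L || ndim > 7L)
    stop(sprintf("corrupt NIfTI dim field in %s", path), call. = FALSE)
  shape <- dims[1 + seq_len(ndim)]
  if (any(shape[-(1:3)] > 1L) || ndim < 3L && prod(shape) == 0L)
    stop(sprintf("only 3D volumes supported: %s has dims %s", path,
                 paste(shape, collapse = "x")), call. = FALSE)
  shape3 <- c(shape, 1L, 1L)[1:3]
  datatype <- rd(raw_hdr[71:72], "integer", 2)
  pixdim <- rd(raw_hdr[77:108], "numeric", 4, n = 8)
  vox_offset <- rd(raw_hdr[109:112], "numeric", 4)
  scl_slope <- rd(raw_hdr[113:116], "numeric", 4)
  scl_inter <- rd(raw_hdr[117:120], "numeric", 4)
  sform_code <- rd(raw_hdr[255:256], "integer", 2)
  qoffset <- rd(raw_hdr[269:280], "numeric", 4, n = 3)
  srow <- matrix(rd(raw_hdr[281:328], "numeric", 4, n = 12), nrow = 3,
                 byrow = TRUE)
  origin <- if (sform_code > 0L) srow[, 4] else qoffset

  dt <- switch(as.character(datatype),
    "2"   = list(what = "integer", size = 1, signed = FALSE),
    "256" = list(what = "integer", size = 1, signed = TRUE),
    "4"   = list(what = "integer", size = 2, signed = TRUE),
    "512" = list(what = "integer", size = 2, signed = FALSE),
    "8"   = list(what = "integer", size = 4, signed = TRUE),
    "16"  = list(what = "numeric", size = 4, signed = TRUE),
    "64"  = list(what = "numeric", size = 8, signed = TRUE),
    stop(sprintf("unsupported NIfTI datatype %d in %s", datatype, path),
         call. = FALSE))

  nvox <- prod(shape3)
  skip <- as.integer(round(vox_offset)) - 348L
  if (skip > 0L) readBin(con, "raw", n = skip)
  vals <- readBin(con, dt$what, n = nvox, size = dt$size,
                  signed = dt$signed, endian = endian)
  if (length(vals) < nvox)
    stop(sprintf("truncated NIfTI data in %s", path), call. = FALSE)
  vals <- as.numeric(vals)
  if (is.finite(scl_slope) && scl_slope != 0 &&
      !(scl_slope == 1 && scl_inter == 0))
    vals <- vals * scl_slope + scl_inter
  volume_grid(array(vals, dim = shape3), spacing = abs(pixdim[2:4]),
              origin = origin, units = units)
}

#' @rdname read_volume
#' @export
read_mask <- function(path, label = "") {
  v <- read_volume(path)
  label_mask(v$data != 0, spacing = v$spacing, origin = v$origin,
             label = label)
}

#' @rdname read_volume
#' @param x A [volume_grid()] or [label_mask()] to serialize.
#' @param datatype "float32" (volumes), "float64", or "uint8" (masks).
#' @return `write_volume`: the path, invisibly.
#' @export
write_volume <- function(x, path, datatype = NULL) {
  if (inherits(x, "label_mask")) {
    if (is.null(datatype)) datatype <- "uint8"
    dat <- x$data + 0L
  } else if (inherits(x, "volume_grid")) {
    if (is.null(datatype)) datatype <- "float32"
    dat <- x$data
  } else stop("`x` must be a volume_grid or label_mask", call. = FALSE)
  code <- switch(datatype, uint8 = 2L, int16 = 4L, int32 = 8L,
                 float32 = 16L, float64 = 64L,
                 stop("unsupported datatype: ", datatype, call. = FALSE))
  size <- switch(datatype, uint8 = 1L, int16 = 2L, int32 = 4L,
                 float32 = 4L, float64 = 8L)
  shape <- dim(dat)

  # assemble the fixed 348-byte header (+4-byte extension flag) in memory;
  # gz connections are not seekable, so the layout is written sequentially
  hdr <- rawConnection(raw(0), "wb")
  wi <- function(v, size) writeBin(as.integer(v), hdr, size = size,
                                   endian = "little")
  wf <- function(v) writeBin(as.numeric(v), hdr, size = 4, endian = "little")
  wi(348L, 4)                                     # sizeof_hdr
  writeBin(raw(36), hdr)                          # data_type..dim_info
  wi(c(3L, shape, 1L, 1L, 1L, 1L), 2)             # dim[8]
  wf(c(0, 0, 0))                                  # intent_p1..p3
  wi(0L, 2)                                       # intent_code
  wi(code, 2)                                     # datatype
  wi(8L * size, 2)                                # bitpix
  wi(0L, 2)                                       # slice_start
  wf(c(1, x$spacing, 0, 0, 0, 0))                 # pixdim[8] (qfac = 1)
  wf(352)                                         # vox_offset
  wf(1); wf(0)                                    # scl_slope, scl_inter
  wi(0L, 2); writeBin(raw(2), hdr)                # slice_end, slice_code, xyzt
  wf(c(0, 0, 0, 0))                               # cal_max..toffset
  wi(c(0L, 0L), 4)                                # glmax, glmin
  writeBin(raw(80 + 24), hdr)                     # descrip, aux_file
  wi(1L, 2); wi(1L, 2)                            # qform_code, sform_code
  wf(c(0, 0, 0))                                  # quatern b,c,d (identity)
  wf(x$origin)                                    # qoffset x,y,z
  wf(c(x$spacing[1], 0, 0, x$origin[1]))          # srow_x
  wf(c(0, x$spacing[2], 0, x$origin[2]))          # srow_y
  wf(c(0, 0, x$spacing[3], x$origin[3]))          # srow_z
  writeBin(raw(16), hdr)                          # intent_name
  writeBin(charToRaw("n+1"), hdr); writeBin(raw(1), hdr)  # magic
  writeBin(raw(4), hdr)                           # extension flag
  bytes <- rawConnectionValue(hdr)
  close(hdr)
  stopifnot(length(bytes) == 352L)

  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  writeBin(bytes, con)
  if (size == 1L) {
    writeBin(as.raw(dat), con)
  } else if (code %in% c(16L, 64L)) {
    writeBin(as.numeric(dat), con, size = size, endian = "little")
  } else {
    writeBin(as.integer(round(dat)), con, size = size, endian = "little")
  }
  invisible(path)
}
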