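# Minimal NIfTI-1 reader/writer. No NIfTI package is available in this
# environment, so the single-file (.nii / .nii.gz) variant of the format is
# implemented directly: 348-byte header, magic "n+1", little-endian, data at
# vox_offset. Orientation is stored through qoffset_* with an identity
# quaternion (axis-aligned grids only, which is all this package produces).

nifti_dtypes <- list(`2` = list(what = "integer", size = 1, signed = FALSE),
                     `4` = list(what = "integer", size = 2, signed = TRUE),
                     `8` = list(what = "integer", size = 4, signed = TRUE),
                     `16` = list(what = "double", size = 4, signed = TRUE),
                     `64` = list(what = "double", size = 8, signed = TRUE))

open_maybe_gz <- function(path, mode) {
  if (grepl("\\.gz$", path)) gzfile(path, mode) else file(path, mode)
}

read_nifti_raw <- function(path) {
  con <- open_maybe_gz(path, "rb")
  on.exit(close(con))
  sizeof_hdr <- readBin(con, "integer", 1, 4, endian = "little")
  if (!identical(sizeof_hdr, 348L))
    stop("not a little-endian NIfTI-1 file: ", path)
  readBin(con, "raw", 36)                       # unused header fields
  dims <- readBin(con, "integer", 8, 2, endian = "little")
  readBin(con, "raw", 14)                       # intent params / codes
  datatype <- readBin(con, "integer", 1, 2, endian = "little")
  bitpix <- readBin(con, "integer", 1, 2, endian = "little")
  readBin(con, "integer", 1, 2, endian = "little")   # slice_start
  pixdim <- readBin(con, "double", 8, 4, endian = "little")
  vox_offset <- readBin(con, "double", 1, 4, endian = "little")
  scl_slope <- readBin(con, "double", 1, 4, endian = "little")
  scl_inter <- readBin(con, "double", 1, 4, endian = "little")
  readBin(con, "raw", 148)                      # slice_end .. quatern_d
  qoffset <- readBin(con, "double", 3, 4, endian = "little")
  readBin(con, "raw", 48)                       # srow matrix
  readBin(con, "raw", 16)                       # intent_name
  magic <- rawToChar(readBin(con, "raw", 4))
  if (!grepl("^n\\+1", magic)) stop("unsupported NIfTI magic in ", path)
  dt <- nifti_dtypes[[as.character(datatype)]]
  if (is.null(dt)) stop("unsupported NIfTI datatype ", datatype)
  ndim <- dims[1]
  shape <- dims[2:(1 + ndim)]
  skip <- vox_offset - 348
  if (skip > 0) readBin(con, "raw", skip)
  n <- prod(shape)
  vals <- readBin(con, dt$what, n, dt$size, signed = dt$signed,
                  endian = "little")
  if (is.finite(scl_slope) && scl_slope != 0 &&
      !(scl_slope == 1 && scl_inter == 0))
    vals <- vals * scl_slope + scl_inter
  arr <- array(vals, dim = shape)
  list(data = arr, spacing = pixdim[2:4], origin = qoffset,
       bitpix = bitpix)
}

write_nifti_raw <- function(arr, path, spacing, origin, datatype = 16L) {
  dt <- nifti_dtypes[[as.character(datatype)]]
  con <- open_maybe_gz(path, "wb")
  on.exit(close(con))
  nd <- length(dim(arr))
  dims <- integer(8)
  dims[1] <- nd
  dims[2:(1 + nd)] <- dim(arr)
  dims[(2 + nd):8] <- 1L
  writeBin(348L, con, 4, endian = "little")
  writeBin(raw(36), con)
  writeBin(as.integer(dims), con, 2, endian = "little")
  writeBin(raw(14), con)
  writeBin(as.integer(datatype), con, 2, endian = "little")
  writeBin(as.integer(dt$size * 8), con, 2, endian = "little")
  writeBin(0L, con, 2, endian = "little")            # slice_start
  pixdim <- c(1, spacing, 1, 1, 1, 1)
  writeBin(as.numeric(pixdim), con, 4, endian = "little")
  writeBin(352, con, 4, endian = "little")           # vox_offset
  writeBin(1, con, 4, endian = "little")             # scl_slope
  writeBin(0, con, 4, endian = "little")             # scl_inter
  writeBin(raw(28), con)                             # slice_end .. glmin
  writeBin(raw(80), con)                             # descrip
  writeBin(raw(24), con)                             # aux_file
  writeBin(1L, con, 2, endian = "little")            # qform_code
  writeBin(0L, con, 2, endian = "little")            # sform_code
  writeBin(c(0, 0, 0), con, 4, endian = "little")    # quatern b,c,d (identity)
  writeBin(as.numeric(origin), con, 4, endian = "little")
  writeBin(numeric(12), con, 4, endian = "little")   # srow (unused)
  writeBin(raw(16), con)                             # intent_name
  writeBin(c(charToRaw("n+1"), as.raw(0)), con)
  writeBin(raw(4), con)                              # pad to 352
  if (dt$what == "integer")
    writeBin(as.integer(arr), con, dt$size, endian = "little")
  else
    writeBin(as.numeric(arr), con, dt$size, endian = "little")
  invisible(path)
}

#' Read / write image volumes and masks as NIfTI-1
#'
#' `read_volume_nifti()` and `write_volume_nifti()` handle scalar volumes
#' (float32 on disk); `read_mask_nifti()` and `write_mask_nifti()` handle
#' integer label masks (uint8); `read_field_nifti()`/`write_field_nifti()`
#' handle 4-D deformation fields with 3 vector components.
#'
#' @param path file path ending in `.nii` or `.nii.gz`.
#' @param vol,mask,field objects to write.
#' @return the read object, or (invisibly) `path` for the writers.
#' @export
read_volume_nifti <- function(path) {
  r <- read_nifti_raw(path)
  if (length(dim(r$data)) != 3L) stop("expected a 3-D volume in ", path)
  image_volume(r$data, r$spacing, r$origin)
}

#' @rdname read_volume_nifti
#' @param provenance provenance tag for the mask.
#' @export
read_mask_nifti <- function(path, provenance = "manual") {
  r <- read_nifti_raw(path)
  annotation_mask(round(r$data), r$spacing, r$origin, provenance)
}

#' @rdname read_volume_nifti
#' @export
write_volume_nifti <- function(vol, path) {
  write_nifti_raw(vol$voxels, path, vol$spacing, vol$origin, 16L)
}

#' @rdname read_volume_nifti
#' @export
write_mask_nifti <- function(mask, path) {
  write_nifti_raw(mask$labels, path, mask$spacing, mask$origin, 2L)
}

#' @rdname read_volume_nifti
#' @export
write_field_nifti <- function(field, path) {
  arr <- field$vectors
  arr[is.na(arr)] <- 0
  write_nifti_raw(arr, path, field$spacing, field$origin, 16L)
}

#' @rdname read_volume_nifti
#' @export
read_field_nifti <- function(path) {
  r <- read_nifti_raw(path)
  if (length(dim(r$data)) != 4L || dim(r$data)[4] != 3L)
    stop("expected a 4-D field with 3 components in ", path)
  deformation_field(r$data, roi = NULL, spacing = r$spacing, origin = r$origin)
}
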