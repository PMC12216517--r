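# Minimal DICOM series importer (explicit VR, little endian, uncompressed
# single-frame images) used to ingest scanner exports once; NIfTI is the
# working format thereafter. Only the geometry and pixel tags needed to build
# an image_volume are parsed.

dcm_read_element <- function(con) {
  grp <- readBin(con, "integer", 1, 2, signed = FALSE, endian = "little")
  if (length(grp) == 0) return(NULL)
  ele <- readBin(con, "integer", 1, 2, signed = FALSE, endian = "little")
  vr <- rawToChar(readBin(con, "raw", 2))
  if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")) {
    readBin(con, "raw", 2)
    len <- readBin(con, "integer", 1, 4, endian = "little")
  } else {
    len <- readBin(con, "integer", 1, 2, signed = FALSE, endian = "little")
  }
  if (len < 0) stop("undefined-length DICOM elements are not supported")
  payload <- readBin(con, "raw", len)
  list(tag = sprintf("%04x%04x", grp, ele), vr = vr, raw = payload)
}

dcm_num <- function(el) as.numeric(strsplit(trimws(rawToChar(el$raw)), "\\\\")[[1]])
dcm_us <- function(el) readBin(el$raw, "integer", length(el$raw) / 2, 2,
                               signed = FALSE, endian = "little")

read_dicom_file <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "raw", 128)
  if (!identical(rawToChar(readBin(con, "raw", 4)), "DICM"))
    stop("missing DICM preamble in ", path)
  out <- list()
  repeat {
    el <- dcm_read_element(con)
    if (is.null(el)) break
    out[[el$tag]] <- el
    if (el$tag == "7fe00010") break
  }
  rows <- dcm_us(out[["00280010"]])
  cols <- dcm_us(out[["00280011"]])
  ps <- dcm_num(out[["00280030"]])
  ipp <- if (!is.null(out[["00200032"]])) dcm_num(out[["00200032"]]) else c(0, 0, 0)
  thick <- if (!is.null(out[["00180050"]])) dcm_num(out[["00180050"]]) else 1
  slope <- if (!is.null(out[["00281053"]])) dcm_num(out[["00281053"]]) else 1
  inter <- if (!is.null(out[["00281052"]])) dcm_num(out[["00281052"]]) else 0
  px <- out[["7fe00010"]]
  if (is.null(px)) stop("no PixelData in ", path)
  vals <- readBin(px$raw, "integer", rows * cols, 2, signed = TRUE,
                  endian = "little")
  # DICOM stores row-major (column index fastest); our arrays are (x, y)
  m <- t(matrix(vals, nrow = cols, ncol = rows))
  m <- m * slope + inter
  list(pixels = t(m), rows = rows, cols = cols, spacing_xy = rev(ps)[c(1, 2)],
       position = ipp, thickness = thick)
}

#' Import a DICOM series as an image volume
#'
#' Reads an uncompressed, explicit-VR little-endian single-frame DICOM series
#' (one file per axial section), sorts sections by their z position, and
#' assembles an [image_volume()]. In-plane spacing comes from PixelSpacing,
#' section spacing from successive ImagePositionPatient z values (falling back
#' to SliceThickness for a single section).
#'
#' @param paths character vector of DICOM file paths (one per section).
#' @return An [image_volume()].
#' @export
read_dicom_series <- function(paths) {
  if (length(paths) < 1) stop("no DICOM files given")
  slices <- lapply(paths, read_dicom_file)
  z <- vapply(slices, function(s) s$position[3], numeric(1))
  ord <- order(z)
  slices <- slices[ord]
  z <- z[ord]
  nx <- slices[[1]]$cols
  ny <- slices[[1]]$rows
  arr <- array(0, dim = c(nx, ny, length(slices)))
  for (k in seq_along(slices)) {
    if (slices[[k]]$cols != nx || slices[[k]]$rows != ny)
      stop("inconsistent section shapes across the series")
    arr[, , k] <- slices[[k]]$pixels
  }
  dz <- if (length(z) > 1) median(diff(z)) else slices[[1]]$thickness
  sp <- c(slices[[1]]$spacing_xy, dz)
  image_volume(arr, spacing = sp, origin = slices[[1]]$position)
}
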