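#' Resample a volume and mask to a target spacing
#'
#' Linearly resamples intensities and nearest-neighbor resamples labels onto a
#' new grid with the requested spacing, preserving the physical extent of the
#' input within one voxel. The canonical working resolution for rectal T2w
#' MRI in this package is `c(0.781, 0.781, 4.0)` mm.
#'
#' @param vol an [image_volume()].
#' @param mask an optional paired [annotation_mask()].
#' @param target_spacing length-3 positive spacing in mm.
#' @return list with elements `volume` and (if a mask was given) `mask`.
#' @export
resample_volume <- function(vol, mask = NULL, target_spacing = c(0.781, 0.781, 4)) {
  target_spacing <- as.numeric(target_spacing)
  if (length(target_spacing) != 3L || any(!is.finite(target_spacing)) ||
      any(target_spacing <= 0))
    stop("target_spacing must be 3 strictly positive values")
  if (!is.null(mask)) stopifnot_same_grid(vol, mask)
  d <- dim(vol$voxels)
  extent <- d * vol$spacing
  nd <- pmax(1L, as.integer(round(extent / target_spacing)))
  idmat <- diag(3)
  zero <- c(0, 0, 0)
  # keep the physical center of the grid fixed
  new_origin <- vol$origin + (d - 1) * vol$spacing / 2 -
    (nd - 1) * target_spacing / 2
  vox <- cpp_warp_volume(vol$voxels, vol$spacing, vol$origin, idmat, zero,
                         NULL, zero, c(1, 1, 1), nd, target_spacing,
                         new_origin, 0, FALSE)
  out <- list(volume = image_volume(vox, target_spacing, new_origin))
  if (!is.null(mask)) {
    lab <- cpp_warp_volume(as.numeric_array(mask$labels), mask$spacing, mask$origin,
                           idmat, zero, NULL, zero, c(1, 1, 1), nd,
                           target_spacing, new_origin, LABEL_BACKGROUND, TRUE)
    out$mask <- annotation_mask(lab, target_spacing, new_origin,
                                mask$provenance)
  }
  out
}

#' Center and crop a volume around its wall ROI
#'
#' Produces an output grid of exactly `target_shape` voxels whose center lies
#' within one voxel of the wall-ROI centroid. Regions falling outside the
#' input are padded with intensity 0 (background label for masks).
#'
#' @param vol an [image_volume()].
#' @param mask the paired [annotation_mask()]; its wall label defines the ROI.
#' @param target_shape integer length-3 voxel counts of the output.
#' @return list with elements `volume` and `mask`.
#' @export
center_crop_to_roi <- function(vol, mask, target_shape) {
  stopifnot_same_grid(vol, mask)
  target_shape <- as.integer(target_shape)
  stopifnot(length(target_shape) == 3L, all(target_shape >= 1L))
  idx <- which_voxels(mask$labels == LABEL_WALL)
  if (nrow(idx) == 0L) stop("empty ROI: mask has no wall voxels")
  cen <- colMeans(idx)                       # 1-based voxel centroid
  start <- round(cen - (target_shape + 1) / 2)  # 0-based offset of output
  new_origin <- vol$origin + start * vol$spacing
  idmat <- diag(3)
  zero <- c(0, 0, 0)
  vox <- cpp_warp_volume(vol$voxels, vol$spacing, vol$origin, idmat, zero,
                         NULL, zero, c(1, 1, 1), target_shape, vol$spacing,
                         new_origin, 0, TRUE)
  lab <- cpp_warp_volume(as.numeric_array(mask$labels), mask$spacing, mask$origin,
                         idmat, zero, NULL, zero, c(1, 1, 1), target_shape,
                         vol$spacing, new_origin, LABEL_BACKGROUND, TRUE)
  list(volume = image_volume(vox, vol$spacing, new_origin),
       mask = annotation_mask(lab, vol$spacing, new_origin, mask$provenance))
}

#' Select the analysis region of a mask
#'
#' Returns the wall voxels to analyze: the single axial section with the
#' largest wall area, the 5 consecutive sections (containing that section)
#' with the largest total wall area, or the whole wall. Ties break toward
#' the lowest section index.
#'
#' @param mask an [annotation_mask()].
#' @param mode one of `"single_section"`, `"five_sections"`, `"whole_volume"`.
#' @return integer matrix of 1-based voxel indices (columns `dim1..dim3`),
#'   with the selected section range in attribute `"sections"`.
#' @export
select_analysis_region <- function(mask,
                                   mode = c("single_section", "five_sections",
                                            "whole_volume")) {
  mode <- match.arg(mode)
  wall <- mask$labels == LABEL_WALL
  counts <- apply(wall, 3, sum)
  if (all(counts == 0)) stop("mask has no wall voxels in any section")
  sections <- switch(mode,
    single_section = which.max(counts),
    five_sections = {
      occupied <- which(counts > 0)
      if (length(occupied) < 5L) {
        warning("fewer than 5 annotated sections; using all available")
        occupied
      } else {
        best <- which.max(counts)
        # consecutive 5-window containing the best section, maximal total area
        starts <- max(1L, best - 4L):min(best, length(counts) - 4L)
        totals <- vapply(starts, function(s) sum(counts[s:(s + 4L)]), numeric(1))
        s0 <- starts[which.max(totals)]
        s0:(s0 + 4L)
      }
    },
    whole_volume = seq_len(dim(wall)[3]))
  keep <- array(FALSE, dim(wall))
  keep[, , sections] <- TRUE
  idx <- which_voxels(wall & keep)
  attr(idx, "sections") <- sections
  idx
}

#' Wall volume in cubic millimeters
#'
#' @param mask an [annotation_mask()].
#' @return wall voxel count times voxel volume, in mm^3.
#' @export
wall_volume <- function(mask) {
  sum(mask$labels == LABEL_WALL) * prod(mask$spacing)
}
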