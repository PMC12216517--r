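#' @useDynLib stodeo, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats median sd quantile cor kmeans kruskal.test wilcox.test
#'   p.adjust hclust cutree as.dist dist rnorm runif rbinom smooth.spline
#'   predict fft setNames aggregate
NULL

# label vocabulary shared by all mask operations
LABEL_BACKGROUND <- 0L
LABEL_WALL <- 1L
LABEL_LUMEN <- 2L

#' Image volume container
#'
#' A 3-D scalar grid with physical voxel spacing and origin. Voxel `(i,j,k)`
#' (1-based in R) is centered at physical position
#' `origin + (c(i,j,k) - 1) * spacing` in mm. The third array axis is the
#' axial (section) axis by convention.
#'
#' @param voxels 3-D numeric array of intensities (finite).
#' @param spacing length-3 positive numeric, mm per voxel along each axis.
#' @param origin length-3 numeric, physical position of voxel (1,1,1) in mm.
#' @return An object of class `image_volume`.
#' @export
image_volume <- function(voxels, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  voxels <- as.array(voxels)
  if (length(dim(voxels)) == 2L) dim(voxels) <- c(dim(voxels), 1L)
  stopifnot(length(dim(voxels)) == 3L)
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be 3 strictly positive finite values")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("origin must be 3 finite values")
  if (any(!is.finite(voxels)))
    stop("voxels must be finite (no NaN/Inf)")
  structure(list(voxels = voxels, spacing = spacing, origin = origin),
            class = "image_volume")
}

#' Annotation mask container
#'
#' Integer labels over the same grid as a paired [image_volume()]:
#' 0 = background, 1 = wall, 2 = lumen.
#'
#' @param labels 3-D integer array with values in \{0, 1, 2\}.
#' @param spacing,origin grid geometry, as in [image_volume()].
#' @param provenance `"manual"` or `"automated"`.
#' @return An object of class `annotation_mask`.
#' @export
annotation_mask <- function(labels, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                            provenance = c("manual", "automated")) {
  provenance <- match.arg(provenance)
  labels <- as.array(labels)
  if (length(dim(labels)) == 2L) dim(labels) <- c(dim(labels), 1L)
  storage.mode(labels) <- "integer"
  if (!all(labels %in% c(LABEL_BACKGROUND, LABEL_WALL, LABEL_LUMEN)))
    stop("mask labels must be in {0 (background), 1 (wall), 2 (lumen)}")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("spacing must be 3 strictly positive values")
  structure(list(labels = labels, spacing = spacing,
                 origin = as.numeric(origin), provenance = provenance),
            class = "annotation_mask")
}

#' @export
print.image_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<image_volume> %d x %d x %d voxels, spacing (%.3f, %.3f, %.3f) mm\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  intensity range [%.4g, %.4g]\n",
              min(x$voxels), max(x$voxels)))
  invisible(x)
}

#' @export
print.annotation_mask <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf("<annotation_mask> %d x %d x %d voxels (%s): %d wall, %d lumen\n",
              d[1], d[2], d[3], x$provenance,
              sum(x$labels == LABEL_WALL), sum(x$labels == LABEL_LUMEN)))
  invisible(x)
}

stopifnot_same_grid <- function(vol, mask) {
  if (!identical(dim(vol$voxels), dim(mask$labels)))
    stop("volume and mask must share the same grid shape")
  if (max(abs(vol$spacing - mask$spacing)) > 1e-8)
    stop("volume and mask must share the same spacing")
}

# physical coordinates (n x 3, mm) of 1-based voxel indices (n x 3)
voxel_to_physical <- function(idx, spacing, origin) {
  idx <- matrix(as.numeric(idx), ncol = 3)
  sweep(sweep(idx - 1, 2, spacing, "*"), 2, origin, "+")
}

# 1-based voxel index matrix of TRUE entries of a logical/0-1 array
which_voxels <- function(arr) {
  which(arr != 0, arr.ind = TRUE)
}

# centroid (physical, mm) of the non-zero voxels of an array
label_centroid <- function(arr, spacing, origin) {
  idx <- which_voxels(arr)
  if (nrow(idx) == 0L) stop("cannot compute centroid of an empty label set")
  colMeans(voxel_to_physical(idx, spacing, origin))
}
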