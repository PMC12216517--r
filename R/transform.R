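#' Composite spatial transform
#'
#' Represents `G(x) = A x + t + u(x)` where `A`/`t` is an affine component and
#' `u` a cubic b-spline free-form displacement on a control grid, all in
#' physical mm. Registration produces `G` mapping patient coordinates to
#' atlas coordinates.
#'
#' @param A 3x3 matrix.
#' @param t length-3 translation (mm).
#' @param coef b-spline control coefficients, array `(ncx, ncy, ncz, 3)` in
#'   mm, or `NULL` for a purely affine transform.
#' @param grid_origin,grid_spacing control-grid geometry (mm).
#' @return object of class `composite_transform`.
#' @export
composite_transform <- function(A = diag(3), t = c(0, 0, 0), coef = NULL,
                                grid_origin = c(0, 0, 0),
                                grid_spacing = c(1, 1, 1)) {
  structure(list(A = A, t = as.numeric(t), coef = coef,
                 grid_origin = as.numeric(grid_origin),
                 grid_spacing = as.numeric(grid_spacing)),
            class = "composite_transform")
}

#' Apply a composite transform to physical points
#'
#' @param transform a [composite_transform()].
#' @param pts n x 3 matrix of physical points (mm).
#' @return n x 3 matrix of mapped points.
#' @export
apply_transform <- function(transform, pts) {
  pts <- matrix(as.numeric(pts), ncol = 3)
  cpp_apply_transform(transform$A, transform$t,
                      if (is.null(transform$coef)) NULL
                      else as.numeric_array(transform$coef),
                      transform$grid_origin, transform$grid_spacing, pts)
}

as.numeric_array <- function(a) {
  d <- dim(a)
  a <- as.numeric(a)
  dim(a) <- d
  a
}

#' Deformation field container
#'
#' Per-voxel displacement 3-vectors (mm) over an atlas-space grid, with a
#' logical ROI marking where the vectors are valid.
#'
#' @param vectors array `(nx, ny, nz, 3)` of displacements in mm.
#' @param roi logical array `(nx, ny, nz)` or `NULL` (everywhere valid).
#' @param spacing,origin grid geometry (mm).
#' @return object of class `deformation_field`.
#' @export
deformation_field <- function(vectors, roi = NULL, spacing = c(1, 1, 1),
                              origin = c(0, 0, 0)) {
  stopifnot(length(dim(vectors)) == 4L, dim(vectors)[4] == 3L)
  if (!is.null(roi)) {
    stopifnot(identical(dim(roi), dim(vectors)[1:3]))
    idx <- which_voxels(roi)
    if (nrow(idx) > 0) {
      vals <- cbind(vectors[cbind(idx, 1)], vectors[cbind(idx, 2)],
                    vectors[cbind(idx, 3)])
      if (any(!is.finite(vals)))
        stop("deformation field has non-finite components inside the ROI")
    }
  }
  structure(list(vectors = vectors, roi = roi, spacing = as.numeric(spacing),
                 origin = as.numeric(origin)),
            class = "deformation_field")
}

#' @export
print.deformation_field <- function(x, ...) {
  d <- dim(x$vectors)[1:3]
  nroi <- if (is.null(x$roi)) prod(d) else sum(x$roi)
  cat(sprintf("<deformation_field> %d x %d x %d grid, %d ROI voxels\n",
              d[1], d[2], d[3], nroi))
  invisible(x)
}

# displacement vectors (n x 3) at the ROI voxels, plus their physical coords
field_roi_vectors <- function(field) {
  roi <- if (is.null(field$roi)) array(TRUE, dim(field$vectors)[1:3]) else field$roi
  idx <- which_voxels(roi)
  v <- cbind(field$vectors[cbind(idx, 1)], field$vectors[cbind(idx, 2)],
             field$vectors[cbind(idx, 3)])
  list(idx = idx, vectors = v,
       points = voxel_to_physical(idx, field$spacing, field$origin))
}

#' Invert a composite transform over a region of interest
#'
#' Fixed-point inversion of `G`: for each atlas-grid voxel `x` the patient
#' point `y` with `G(y) = x` is found iteratively; the residual
#' `|G(y) - x|` is recorded. Voxels where the transform's Jacobian
#' determinant is non-positive (locally non-invertible folds) are flagged and
#' excluded from the returned ROI.
#'
#' @param forward a [composite_transform()] mapping patient to atlas space.
#' @param roi logical 3-D array over the atlas grid (voxels to invert), or
#'   `NULL` for the whole grid.
#' @param spacing,origin atlas grid geometry (mm).
#' @param tolerance_mm target residual, default 0.1 mm.
#' @param max_iters fixed-point iteration cap, default 50.
#' @return list with `points` (n x 3 inverse-mapped points), `displacement`
#'   (n x 3, `points - x`), `residual_mm`, `roi_index` (voxel indices kept),
#'   `n_folded` (excluded voxels), and `ok_fraction` (residual <= tolerance).
#' @export
invert_transform <- function(forward, roi, spacing, origin,
                             tolerance_mm = 0.1, max_iters = 50) {
  if (is.null(dim(roi))) stop("roi must be a logical 3-D array")
  idx <- which_voxels(roi)
  if (nrow(idx) == 0L) stop("empty ROI")
  x <- voxel_to_physical(idx, spacing, origin)
  inv <- cpp_invert_points(forward$A, forward$t,
                           if (is.null(forward$coef)) NULL
                           else as.numeric_array(forward$coef),
                           forward$grid_origin, forward$grid_spacing,
                           x, max_iters, tolerance_mm / 10)
  detj <- jacobian_determinant(forward, inv$points, step = min(spacing) / 2)
  folded <- detj <= 0
  keep <- !folded
  list(points = inv$points[keep, , drop = FALSE],
       displacement = inv$points[keep, , drop = FALSE] - x[keep, , drop = FALSE],
       residual_mm = inv$residual[keep],
       roi_index = idx[keep, , drop = FALSE],
       n_folded = sum(folded),
       ok_fraction = mean(inv$residual[keep] <= tolerance_mm))
}

# det(dG/dx) by central differences at given points
jacobian_determinant <- function(transform, pts, step = 0.5) {
  n <- nrow(pts)
  J <- vector("list", 3)
  for (d in 1:3) {
    e <- matrix(0, n, 3)
    e[, d] <- step
    J[[d]] <- (apply_transform(transform, pts + e) -
               apply_transform(transform, pts - e)) / (2 * step)
  }
  J[[1]][, 1] * (J[[2]][, 2] * J[[3]][, 3] - J[[2]][, 3] * J[[3]][, 2]) -
  J[[1]][, 2] * (J[[2]][, 1] * J[[3]][, 3] - J[[2]][, 3] * J[[3]][, 1]) +
  J[[1]][, 3] * (J[[2]][, 1] * J[[3]][, 2] - J[[2]][, 2] * J[[3]][, 1])
}

# random smooth b-spline transform generator (test/benchmark utility):
# control-point displacements drawn N(0, sd), sd chosen small relative to the
# knot spacing so the transform stays invertible
#' Random smooth b-spline transform
#'
#' Draws control-point displacements from a Gaussian with SD
#' `relative_amplitude * grid_spacing`, which keeps the transform comfortably
#' diffeomorphic for `relative_amplitude` well below ~0.4.
#'
#' @param domain_min,domain_max physical corners of the domain (mm).
#' @param grid_spacing control-point spacing (mm).
#' @param relative_amplitude displacement SD as a fraction of grid spacing.
#' @param seed integer seed.
#' @return a [composite_transform()].
#' @export
random_bspline_transform <- function(domain_min, domain_max,
                                     grid_spacing = c(15, 15, 15),
                                     relative_amplitude = 0.1, seed = 1L) {
  set.seed(seed)
  nc <- pmax(4L, as.integer(ceiling((domain_max - domain_min) / grid_spacing)) + 4L)
  go <- domain_min - 2 * grid_spacing
  coef <- array(rnorm(prod(nc) * 3), dim = c(nc, 3))
  for (d in 1:3) coef[, , , d] <- coef[, , , d] * relative_amplitude * grid_spacing[d]
  composite_transform(diag(3), c(0, 0, 0), coef, go, grid_spacing)
}
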