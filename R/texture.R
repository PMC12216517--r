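# Texture radiomics over 2-D axial sections: Gabor filter bank, Sobel
# gradient (including the +/-45 degree diagonal variants named XY and YX),
# and CoLlAGe (co-occurrence of local anisotropic gradient orientations,
# Haralick statistics over locally dominant gradient directions).

# 2-D convolution with reflected boundary handling (same-size output)
conv2_reflect <- function(img, kern) {
  kr <- (dim(kern)[1] - 1) / 2
  kc <- (dim(kern)[2] - 1) / 2
  n1 <- dim(img)[1]
  n2 <- dim(img)[2]
  ridx <- function(i, n) {
    i <- ((i - 1) %% (2 * n)) + 1
    ifelse(i > n, 2 * n + 1 - i, i)
  }
  pad <- img[ridx(seq(1 - kr, n1 + kr), n1), ridx(seq(1 - kc, n2 + kc), n2),
             drop = FALSE]
  p1 <- dim(pad)[1]
  p2 <- dim(pad)[2]
  kfull <- matrix(0, p1, p2)
  kfull[1:dim(kern)[1], 1:dim(kern)[2]] <- kern[dim(kern)[1]:1, dim(kern)[2]:1]
  out <- Re(fft(fft(pad) * fft(kfull), inverse = TRUE)) / (p1 * p2)
  out[(2 * kr + 1):(2 * kr + n1), (2 * kc + 1):(2 * kc + n2), drop = FALSE]
}

# axis-direction naming shared by Gabor and Sobel banks: X = 0 deg (along
# first array axis), XY = +45 deg, Y = 90 deg, YX = -45 deg
texture_directions <- c(X = 0, XY = 45, Y = 90, YX = 135)

#' Gabor filter kernel and response
#'
#' Real part of a 2-D Gabor filter: an oriented sinusoidal carrier under a
#' Gaussian envelope, DC-corrected so a constant image yields zero response.
#'
#' @param section 2-D numeric matrix (an axial image section).
#' @param orientation carrier orientation in degrees.
#' @param wavelength carrier wavelength in voxels.
#' @param bandwidth half-response spatial-frequency bandwidth in octaves
#'   (sets the envelope width).
#' @return response matrix, same size as `section`; the kernel itself is in
#'   attribute `"kernel"`.
#' @export
gabor_response <- function(section, orientation, wavelength, bandwidth = 1) {
  sigma <- wavelength / pi * sqrt(log(2) / 2) *
    (2^bandwidth + 1) / (2^bandwidth - 1)
  half <- max(3L, ceiling(3 * sigma))
  g <- seq(-half, half)
  th <- orientation * pi / 180
  xr <- outer(g, g, function(x, y) x * cos(th) + y * sin(th))
  yr <- outer(g, g, function(x, y) -x * sin(th) + y * cos(th))
  kern <- exp(-(xr^2 + yr^2) / (2 * sigma^2)) * cos(2 * pi * xr / wavelength)
  kern <- kern - mean(kern) * exp(-(xr^2 + yr^2) / (2 * sigma^2)) /
    mean(exp(-(xr^2 + yr^2) / (2 * sigma^2)))      # zero DC gain
  if (min(dim(section)) < dim(kern)[1])
    warning("ROI section smaller than the Gabor kernel support")
  out <- conv2_reflect(section, kern)
  attr(out, "kernel") <- kern
  out
}

sobel_kernels <- local({
  # rows index the first (x) array axis: X differentiates along x
  sx <- matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, byrow = TRUE)
  sy <- t(sx)
  # diagonal variants: gradient along the +/-45 degree axes
  sxy <- matrix(c(0, 1, 2, -1, 0, 1, -2, -1, 0), 3, byrow = TRUE)
  syx <- matrix(c(-2, -1, 0, -1, 0, 1, 0, 1, 2), 3, byrow = TRUE)
  list(X = sx, Y = sy, XY = sxy, YX = syx)
})

#' Sobel gradient response
#'
#' Sobel edge filtering of a 2-D section along the named direction: `"X"`,
#' `"Y"`, or the diagonal variants `"XY"` (+45 deg) and `"YX"` (-45 deg).
#'
#' @param section 2-D numeric matrix.
#' @param direction one of `"X"`, `"Y"`, `"XY"`, `"YX"`.
#' @return response matrix, same size as `section`.
#' @export
sobel_gradient <- function(section, direction = c("X", "Y", "XY", "YX")) {
  direction <- match.arg(direction)
  conv2_reflect(section, sobel_kernels[[direction]])
}

# Haralick measures of a (sparse) co-occurrence matrix given as a data.frame
# of (i, j, count); levels are the distinct quantized orientation codes
haralick_from_pairs <- function(pi_, pj_, cnt) {
  p <- cnt / sum(cnt)
  idm <- sum(p / (1 + (pi_ - pj_)^2))
  keyi <- sort(unique(c(pi_, pj_)))
  px <- vapply(keyi, function(l) sum(p[pi_ == l]), numeric(1))
  py <- vapply(keyi, function(l) sum(p[pj_ == l]), numeric(1))
  hx <- -sum(px[px > 0] * log(px[px > 0]))
  hy <- -sum(py[py > 0] * log(py[py > 0]))
  hxy <- -sum(p * log(p))
  pxy <- px[match(pi_, keyi)] * py[match(pj_, keyi)]
  hxy1 <- -sum(p * log(pmax(pxy, 1e-300)))
  info1 <- if (max(hx, hy) > 0) (hxy - hxy1) / max(hx, hy) else 0
  mux <- sum(keyi * px)
  muy <- sum(keyi * py)
  sx <- sqrt(sum((keyi - mux)^2 * px))
  sy <- sqrt(sum((keyi - muy)^2 * py))
  corr <- if (sx > 0 && sy > 0)
    (sum(pi_ * pj_ * p) - mux * muy) / (sx * sy) else 0
  c(info1 = info1, idm = idm,
    energy = sum(p^2), entropy = hxy,
    contrast = sum((pi_ - pj_)^2 * p), correlation = corr)
}

#' CoLlAGe feature maps for a 2-D section
#'
#' Co-occurrence of Local Anisotropic Gradient Orientations: per ROI voxel,
#' (1) image gradients along x and y; (2) the locally dominant gradient
#' orientation from the principal component of the gradient vectors in the
#' voxel's `window_size` neighborhood; (3) orientations quantized to
#' `n_levels` over `[0, pi)`; (4) a symmetric gray-level co-occurrence matrix
#' of the quantized orientations within the window (unit offsets along both
#' axes); (5) Haralick measures of that matrix — information measure of
#' correlation 1 (`info1`, in `[-1, 0]`), inverse difference moment (`idm`,
#' in `(0, 1]`), energy, entropy, contrast and correlation.
#'
#' Windows whose gradients all vanish have no defined orientation; such
#' voxels are assigned a single neutral level (giving the degenerate
#' convention idm = 1, info1 = 0) and counted in attribute `"n_neutral"`.
#'
#' @param section 2-D numeric matrix.
#' @param roi logical matrix marking ROI voxels.
#' @param window_size odd window edge length (default 5).
#' @param n_levels orientation quantization levels over `[0, pi)`.
#' @return list of per-voxel feature maps (matrices, NA outside ROI), one
#'   per Haralick measure.
#' @export
collage_features <- function(section, roi, window_size = 5, n_levels = 64) {
  stopifnot(window_size %% 2 == 1)
  if (!any(roi)) stop("empty ROI")
  gx <- conv2_reflect(section, sobel_kernels$X)
  gy <- conv2_reflect(section, sobel_kernels$Y)
  n1 <- nrow(section)
  n2 <- ncol(section)
  half <- (window_size - 1) / 2
  # dominant orientation per voxel: principal eigenvector of the 2x2 gradient
  # scatter matrix accumulated over the voxel's window (box sums)
  box <- matrix(1, window_size, window_size)
  sxx <- conv2_reflect(gx * gx, box)
  syy <- conv2_reflect(gy * gy, box)
  sxy <- conv2_reflect(gx * gy, box)
  # principal direction of [[sxx, sxy], [sxy, syy]]
  theta <- 0.5 * atan2(2 * sxy, sxx - syy)
  theta <- theta %% pi
  theta[theta >= pi - 1e-9] <- 0        # wrap FFT-noise-level angles at pi
  mag2 <- sxx + syy
  neutral <- mag2 < 1e-18
  lev <- floor(theta / pi * n_levels)
  lev[lev > n_levels - 1] <- n_levels - 1
  lev <- lev + 1
  lev[neutral] <- 0                        # neutral code
  n_neutral_roi <- sum(neutral & roi)

  measures <- c("info1", "idm", "energy", "entropy", "contrast", "correlation")
  maps <- lapply(measures, function(m) matrix(NA_real_, n1, n2))
  names(maps) <- measures
  ridx <- which(roi, arr.ind = TRUE)
  for (q in seq_len(nrow(ridx))) {
    i <- ridx[q, 1]
    j <- ridx[q, 2]
    i0 <- max(1, i - half); i1 <- min(n1, i + half)
    j0 <- max(1, j - half); j1 <- min(n2, j + half)
    w <- lev[i0:i1, j0:j1, drop = FALSE]
    # symmetric co-occurrence at unit offsets along both axes
    a <- c(w[-nrow(w), ], w[, -ncol(w)])
    b <- c(w[-1, ], w[, -1])
    pi_ <- c(a, b)
    pj_ <- c(b, a)
    key <- paste(pi_, pj_)
    tab <- table(key)
    ij <- do.call(rbind, strsplit(names(tab), " "))
    h <- haralick_from_pairs(as.numeric(ij[, 1]), as.numeric(ij[, 2]),
                             as.numeric(tab))
    for (m in measures) maps[[m]][i, j] <- h[[m]]
  }
  attr(maps, "n_neutral") <- n_neutral_roi
  maps
}

#' First-order aggregation of a response map over an ROI
#'
#' @param map numeric matrix/array of per-voxel responses.
#' @param roi logical mask of the same shape.
#' @return named vector: median, variance, std, skewness (moment-based),
#'   kurtosis (excess); degenerate (constant) maps return 0 for
#'   variance/skewness/kurtosis.
#' @export
aggregate_first_order <- function(map, roi) {
  x <- map[roi]
  x <- x[is.finite(x)]
  if (length(x) == 0L) stop("empty ROI in feature aggregation")
  sk <- moment_skew_kurt(x)
  c(Median = median(x), Variance = if (length(x) > 1) stats::var(x) else 0,
    Std = if (length(x) > 1) sd(x) else 0,
    Skewness = unname(sk[1]), Kurtosis = unname(sk[2]))
}

#' Extract the texture feature set for a patient volume
#'
#' Computes the implemented texture bank — Gabor (4 orientations x
#' `gabor_wavelengths`), Sobel (X, Y, XY, YX) and CoLlAGe (6 Haralick
#' measures at `window_size`) — per axial section of the analysis region,
#' pools per-voxel responses across the region's sections, and aggregates
#' each map with the five first-order statistics. Keys follow the
#' `"<Statistic>—<family> <direction/measure>"` convention (e.g.
#' `"Skewness—Gabor XY w=4"`, `"Variance—CoLlAGe idm ws=5"`).
#'
#' @param vol an [image_volume()].
#' @param mask the paired [annotation_mask()].
#' @param region_mode `"single_section"`, `"five_sections"`,
#'   `"whole_volume"`.
#' @param gabor_wavelengths carrier wavelengths in voxels.
#' @param window_size CoLlAGe window size.
#' @return named numeric vector of texture features; the bank size is
#'   attached as attribute `"bank_size"`.
#' @export
extract_texture_features <- function(vol, mask,
                                     region_mode = c("single_section",
                                                     "five_sections",
                                                     "whole_volume"),
                                     gabor_wavelengths = c(2, 4, 8),
                                     window_size = 5) {
  region_mode <- match.arg(region_mode)
  stopifnot_same_grid(vol, mask)
  idx <- select_analysis_region(mask, region_mode)
  sections <- sort(unique(idx[, 3]))
  pooled <- list()
  for (k in sections) {
    sec <- vol$voxels[, , k]
    roi <- mask$labels[, , k] == LABEL_WALL
    if (!any(roi)) next
    maps <- list()
    for (dn in names(texture_directions))
      for (wl in gabor_wavelengths)
        maps[[sprintf("Gabor %s w=%g", dn, wl)]] <-
          gabor_response(sec, texture_directions[[dn]], wl)
    for (dn in names(texture_directions))
      maps[[sprintf("Gradient Sobel %s", dn)]] <- sobel_gradient(sec, dn)
    cf <- collage_features(sec, roi, window_size)
    for (m in names(cf))
      maps[[sprintf("CoLlAGe %s ws=%d", m, window_size)]] <- cf[[m]]
    for (fam in names(maps))
      pooled[[fam]] <- c(pooled[[fam]], maps[[fam]][roi])
  }
  out <- numeric(0)
  for (fam in names(pooled)) {
    ag <- aggregate_first_order(pooled[[fam]], rep(TRUE, length(pooled[[fam]])))
    names(ag) <- sprintf("%s—%s", names(ag), fam)
    out <- c(out, ag)
  }
  attr(out, "bank_size") <- length(out)
  out
}
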