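#' Displacement magnitude field
#'
#' Per-voxel Euclidean norm of the deformation vector,
#' `D = sqrt(dx^2 + dy^2 + dz^2)`, in mm, over the field's ROI.
#'
#' @param field a [deformation_field()].
#' @return object of class `magnitude_field`: `values` (numeric, per ROI
#'   voxel), `idx` (voxel indices), plus grid geometry.
#' @export
magnitude_field <- function(field) {
  rv <- field_roi_vectors(field)
  # explicit three-term sum: plain double arithmetic, bit-identical to an
  # element-wise recomputation (rowSums accumulates in extended precision)
  vals <- sqrt(rv$vectors[, 1]^2 + rv$vectors[, 2]^2 + rv$vectors[, 3]^2)
  structure(list(values = vals, idx = rv$idx, points = rv$points,
                 spacing = field$spacing, origin = field$origin),
            class = "magnitude_field")
}

# moment-based (biased) sample skewness and excess kurtosis; degenerate
# (zero-variance) samples return 0 by convention
moment_skew_kurt <- function(x) {
  n <- length(x)
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 < 1e-24) return(c(skewness = 0, kurtosis = 0))
  m3 <- mean((x - m)^3)
  m4 <- mean((x - m)^4)
  c(skewness = m3 / m2^1.5, kurtosis = m4 / m2^2 - 3)
}

#' First-order statistics of the magnitude field
#'
#' The four-element magnitude descriptor: median, standard deviation
#' (n-1 denominator), moment-based skewness, and excess kurtosis of the
#' per-voxel displacement magnitudes. A constant field returns
#' `(k, 0, 0, 0)`.
#'
#' @param mag a [magnitude_field()] or numeric vector of magnitudes.
#' @return named numeric vector
#'   `(median_mag, std_mag, skew_mag, kurt_mag)`.
#' @export
magnitude_statistics <- function(mag) {
  x <- if (inherits(mag, "magnitude_field")) mag$values else as.numeric(mag)
  if (length(x) == 0L) stop("empty ROI: no magnitudes to summarize")
  sk <- moment_skew_kurt(x)
  c(median_mag = median(x), std_mag = if (length(x) > 1) sd(x) else 0,
    skew_mag = unname(sk[1]), kurt_mag = unname(sk[2]))
}

# 6-neighbour index pairs for a set of voxels (positions within the subset)
neighbour_pairs <- function(idx, dims) {
  key <- (idx[, 1] - 1) + dims[1] * ((idx[, 2] - 1) + dims[2] * (idx[, 3] - 1))
  lut <- integer(prod(dims))
  lut[key + 1] <- seq_len(nrow(idx))
  offs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                c(0, 0, 1), c(0, 0, -1))
  nb <- matrix(0L, nrow(idx), 6)
  for (o in seq_len(6)) {
    nidx <- sweep(idx, 2, offs[o, ], "+")
    ok <- nidx[, 1] >= 1 & nidx[, 1] <= dims[1] &
          nidx[, 2] >= 1 & nidx[, 2] <= dims[2] &
          nidx[, 3] >= 1 & nidx[, 3] <= dims[3]
    nkey <- (nidx[, 1] - 1) + dims[1] * ((nidx[, 2] - 1) +
                                         dims[2] * (nidx[, 3] - 1))
    hit <- integer(nrow(idx))
    hit[ok] <- lut[nkey[ok] + 1]
    nb[, o] <- hit                      # 0 = no neighbour in subset
  }
  nb
}

#' Isolate the high-deformation region by MRF clustering
#'
#' Labels the ROI voxels into `n_classes` by iterated conditional modes over
#' a Gaussian-likelihood plus Potts-prior energy (spatial regularization
#' weight `beta`), initialized by seeded k-means on the magnitudes, and
#' returns the voxel set of the class with the highest mean magnitude.
#' Defaults follow the published setting: 6 classes, 8 iterations,
#' label-field potential 0.5.
#'
#' @param mag a [magnitude_field()].
#' @param n_classes number of magnitude classes.
#' @param n_iters ICM iterations.
#' @param beta Potts prior weight.
#' @param seed seed for the k-means initialization.
#' @param merge_gap classes whose mean magnitudes differ by less than
#'   `merge_gap` times the magnitude SD are treated as one level set when
#'   selecting the top class (resolves the piecewise-constant degeneracy of
#'   running 6 classes on fewer true levels).
#' @return logical vector over the ROI voxels (`TRUE` = high-deformation
#'   region), with the full label vector in attribute `"labels"`.
#' @export
mrf_isolate_high_deformation <- function(mag, n_classes = 6, n_iters = 8,
                                         beta = 0.5, seed = 1L,
                                         merge_gap = 0.2) {
  x <- mag$values
  n <- length(x)
  if (n == 0L) stop("empty ROI")
  ux <- unique(round(x, 12))
  if (n < n_classes || length(ux) < n_classes) {
    if (length(ux) == 1L) {
      # constant field: single effective class, whole ROI returned
      out <- rep(TRUE, n)
      attr(out, "labels") <- rep(1L, n)
      return(out)
    }
    warning("ROI smaller than the class count; falling back to ",
            "top-quantile thresholding")
    out <- x >= quantile(x, 1 - 1 / n_classes)
    attr(out, "labels") <- as.integer(out) + 1L
    return(out)
  }
  set.seed(seed)
  km <- kmeans(x, centers = n_classes, nstart = 3, iter.max = 50)
  lab <- km$cluster
  dims <- if (!is.null(mag$idx)) apply(mag$idx, 2, max) else NULL
  nb <- neighbour_pairs(mag$idx, dims)
  for (it in seq_len(n_iters)) {
    mu <- vapply(seq_len(n_classes), function(k) mean(x[lab == k]), numeric(1))
    s2 <- vapply(seq_len(n_classes),
                 function(k) max(stats::var(x[lab == k]), 1e-8), numeric(1))
    mu[!is.finite(mu)] <- Inf          # emptied class: never chosen
    s2[!is.finite(s2)] <- 1
    # neighbour label counts per class
    en <- matrix(0, n, n_classes)
    for (k in seq_len(n_classes)) {
      same <- matrix(0, n, 6)
      for (o in 1:6) {
        hit <- nb[, o]
        same[hit > 0, o] <- as.numeric(lab[hit[hit > 0]] == k)
      }
      nvalid <- rowSums(nb > 0)
      disagree <- nvalid - rowSums(same)
      en[, k] <- 0.5 * log(2 * pi * s2[k]) +
        (x - mu[k])^2 / (2 * s2[k]) + beta * disagree
    }
    newlab <- max.col(-en, ties.method = "first")
    if (all(newlab == lab)) break
    lab <- newlab
  }
  mu <- vapply(seq_len(n_classes),
               function(k) if (any(lab == k)) mean(x[lab == k]) else -Inf,
               numeric(1))
  # classes whose means sit closer than merge_gap x SD(x) are statistically
  # indistinguishable level sets (a piecewise-constant field splits each
  # plateau across several of the 6 classes); merge them before picking the
  # top group so the returned region covers the whole high plateau
  live <- which(is.finite(mu))
  ord <- live[order(mu[live])]
  gap_tol <- merge_gap * sd(x)
  grp <- cumsum(c(1, diff(mu[ord]) > gap_tol))
  top_group <- ord[grp == max(grp)]
  out <- lab %in% top_group
  attr(out, "labels") <- lab
  out
}

#' Deformation angles relative to the lumen centroid
#'
#' For each selected voxel, the angle between its displacement vector `v'`
#' and the reference vector `v0` pointing from the voxel to the lumen
#' centroid: `theta = arccos(v'.v0 / (|v'||v0|))` in degrees. 0 deg =
#' displacement straight toward the lumen (inward), 180 deg = straight away
#' (outward). Zero-displacement voxels have no defined angle; they are
#' skipped and counted in attribute `"n_skipped"`.
#'
#' @param field a [deformation_field()].
#' @param lumen_centroid length-3 physical point (mm), or an n x 3 matrix of
#'   per-voxel reference centroids (e.g., per-section in-plane centroids).
#' @param region logical vector over the field ROI selecting voxels (e.g.,
#'   the MRF high-deformation set), or `NULL` for all ROI voxels.
#' @return numeric vector of angles in degrees.
#' @export
orientation_field <- function(field, lumen_centroid, region = NULL) {
  rv <- field_roi_vectors(field)
  keep <- if (is.null(region)) rep(TRUE, nrow(rv$idx)) else region
  v <- rv$vectors[keep, , drop = FALSE]
  p <- rv$points[keep, , drop = FALSE]
  cm <- if (is.matrix(lumen_centroid)) lumen_centroid[keep, , drop = FALSE]
        else matrix(lumen_centroid, nrow(p), 3, byrow = TRUE)
  v0 <- cm - p
  nv <- sqrt(rowSums(v^2))
  n0 <- sqrt(rowSums(v0^2))
  valid <- nv > 1e-12 & n0 > 1e-12
  cosang <- rowSums(v * v0)[valid] / (nv[valid] * n0[valid])
  ang <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi
  attr(ang, "n_skipped") <- sum(!valid)
  ang
}

#' Five-bin orientation histogram
#'
#' Quantizes deformation angles into the five bins 0-20, 20-80, 80-100,
#' 100-160 and 160-180 degrees and normalizes to sum 1. Bin edges are
#' assigned so that 20 deg falls in bin 2 and the mapping
#' `theta -> 180 - theta` (negating every displacement vector) exchanges bin
#' k with bin 6-k exactly: bins 1-5 are `[0,20)`, `[20,80)`, `[80,100]`,
#' `(100,160]`, `(160,180]`.
#'
#' @param angles numeric vector of angles in degrees (from
#'   [orientation_field()]).
#' @return numeric length-5 vector summing to 1, or all zeros (with a
#'   warning) when no valid angle exists.
#' @export
orientation_histogram <- function(angles) {
  angles <- angles[is.finite(angles)]
  if (length(angles) == 0L) {
    warning("no valid deformation angles; returning an all-zero histogram")
    return(setNames(numeric(5), paste0("fo_bin", 1:5)))
  }
  counts <- c(sum(angles < 20),
              sum(angles >= 20 & angles < 80),
              sum(angles >= 80 & angles <= 100),
              sum(angles > 100 & angles <= 160),
              sum(angles > 160))
  setNames(counts / length(angles), paste0("fo_bin", 1:5))
}

# per-voxel in-plane lumen centroid: for each ROI voxel, the centroid of the
# lumen label within the same axial section (falls back to the nearest
# section carrying lumen)
section_lumen_centroids <- function(mask, idx) {
  lumen <- mask$labels == LABEL_LUMEN
  nz <- dim(lumen)[3]
  cent <- matrix(NA_real_, nz, 3)
  for (k in seq_len(nz)) {
    sl <- which(lumen[, , k], arr.ind = TRUE)
    if (nrow(sl) > 0)
      cent[k, ] <- colMeans(voxel_to_physical(cbind(sl, k), mask$spacing,
                                              mask$origin))
  }
  have <- which(!is.na(cent[, 1]))
  if (length(have) == 0L) stop("mask has no lumen label; centroid undefined")
  ks <- idx[, 3]
  nearest <- vapply(ks, function(k) have[which.min(abs(have - k))], integer(1))
  cent[nearest, , drop = FALSE]
}

#' Compute the full StODeO descriptor
#'
#' Composes the magnitude and orientation descriptors: magnitude statistics
#' are computed over the full analysis region (selected by `region_mode`),
#' orientations only over the MRF-isolated high-deformation subset, relative
#' to the lumen centroid. By default the centroid is the in-plane lumen
#' centroid of each voxel's own axial section (`centroid_mode = "section"`),
#' which keeps the inward/outward reading purely radial for tubular organs;
#' `"volume"` uses the global 3-D lumen centroid.
#'
#' @param field a [deformation_field()] over the atlas grid.
#' @param mask an [annotation_mask()] on the same grid providing wall/lumen
#'   labels (e.g., the warped patient mask attached by
#'   [extract_displacements()]).
#' @param region_mode `"single_section"`, `"five_sections"` or
#'   `"whole_volume"`.
#' @param centroid_mode `"section"` or `"volume"`.
#' @param mrf_params list of MRF settings (`n_classes`, `n_iters`, `beta`,
#'   `seed`).
#' @param magnitude_on `"full_roi"` (default) or `"mrf_region"`: where the
#'   magnitude statistics are computed.
#' @return object of class `stodeo_descriptor`: `f_m` (4 statistics), `f_o`
#'   (5-bin histogram), `mrf_region` (logical over analysis voxels),
#'   `n_voxels`, `region_mode`.
#' @export
compute_stodeo <- function(field, mask,
                           region_mode = c("single_section", "five_sections",
                                           "whole_volume"),
                           centroid_mode = c("section", "volume"),
                           mrf_params = list(n_classes = 6, n_iters = 8,
                                             beta = 0.5, seed = 1L),
                           magnitude_on = c("full_roi", "mrf_region")) {
  region_mode <- match.arg(region_mode)
  centroid_mode <- match.arg(centroid_mode)
  magnitude_on <- match.arg(magnitude_on)
  stopifnot(identical(dim(mask$labels), dim(field$vectors)[1:3]))

  sel_idx <- select_analysis_region(mask, region_mode)
  sel <- array(FALSE, dim(mask$labels))
  sel[sel_idx] <- TRUE
  roi <- if (is.null(field$roi)) sel else (field$roi & sel)
  if (!any(roi)) stop("empty analysis region")
  sub <- deformation_field(field$vectors, roi = roi, spacing = field$spacing,
                           origin = field$origin)
  mag <- magnitude_field(sub)

  if (all(mag$values == 0)) {
    f_m <- c(median_mag = 0, std_mag = 0, skew_mag = 0, kurt_mag = 0)
    warning("zero deformation field; orientation histogram undefined")
    f_o <- suppressWarnings(orientation_histogram(numeric(0)))
    return(structure(list(f_m = f_m, f_o = f_o,
                          mrf_region = rep(TRUE, length(mag$values)),
                          n_voxels = length(mag$values),
                          region_mode = region_mode),
                     class = "stodeo_descriptor"))
  }

  high <- mrf_isolate_high_deformation(mag, mrf_params$n_classes,
                                       mrf_params$n_iters, mrf_params$beta,
                                       mrf_params$seed)
  f_m <- magnitude_statistics(if (magnitude_on == "full_roi") mag$values
                              else mag$values[high])
  cm <- if (centroid_mode == "section")
    section_lumen_centroids(mask, mag$idx)
  else matrix(label_centroid(mask$labels == LABEL_LUMEN, mask$spacing,
                             mask$origin),
              nrow(mag$idx), 3, byrow = TRUE)
  ang <- orientation_field(sub, cm, region = as.logical(high))
  f_o <- orientation_histogram(ang)
  structure(list(f_m = f_m, f_o = f_o, mrf_region = as.logical(high),
                 n_voxels = length(mag$values), region_mode = region_mode,
                 n_angle_skipped = attr(ang, "n_skipped")),
            class = "stodeo_descriptor")
}

#' @export
print.stodeo_descriptor <- function(x, ...) {
  cat("<stodeo_descriptor>", x$region_mode, "on", x$n_voxels, "wall voxels\n")
  cat("  f_m:", paste(sprintf("%s=%.4g", names(x$f_m), x$f_m),
                      collapse = ", "), "\n")
  cat("  f_o:", paste(sprintf("%.3f", x$f_o), collapse = " "), "\n")
  invisible(x)
}

#' @export
as.data.frame.stodeo_descriptor <- function(x, ...) {
  as.data.frame(c(as.list(x$f_m), as.list(x$f_o),
                  list(region_mode = x$region_mode)))
}
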