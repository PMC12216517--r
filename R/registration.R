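#' Registration engine settings
#'
#' Controls the staged rigid / affine / b-spline registration. The similarity
#' metric defaults to normalized mutual information (robust to intensity
#' variation across scanners); `"ssd"` is available for same-modality or
#' distance-transform channels (used during atlas construction).
#'
#' @param metric `"nmi"` or `"ssd"`.
#' @param nbins joint-histogram bins for NMI.
#' @param stages subset of `c("rigid", "affine", "bspline")`, in order.
#' @param levels in-plane downsampling factors per resolution level
#'   (coarse to fine).
#' @param grid_spacing_mm b-spline control-point spacing per level (mm).
#' @param steps_mm candidate control-point step sizes per level, coarse to
#'   fine (mm).
#' @param passes coordinate-descent sweeps per step size.
#' @param rigid_maxit,affine_maxit Nelder-Mead iteration caps.
#' @param mask_dilate_mm if not `NULL`, restrict the metric to fixed-image
#'   voxels within this distance of the wall ROI (speeds up and focuses the
#'   alignment); `NULL` uses the whole overlap region.
#' @param sample_stride metric sample stride in voxels at each level.
#' @param smooth_factor pyramid Gaussian blur strength (sigma = spacing x
#'   factor x smooth_factor, in-plane).
#' @param sync_passes synchronized (collective line-search) b-spline passes
#'   per step size, run before the greedy sweeps.
#' @param bending_lambda weight of the bending-energy penalty on the control
#'   lattice (per mm^2); keeps the free-form field smooth and invertible.
#' @param axes logical length-3: which physical axes the transform may move.
#'   Disabling an axis removes a gauge freedom when the anatomy is nearly
#'   invariant along it (e.g., axial motion for a straight tube phantom).
#' @param rotations allow rigid rotations; disable for rotationally
#'   symmetric structure channels where rotation about the axis is a gauge
#'   freedom.
#' @param inverse_tolerance_mm inverse-consistency tolerance.
#' @param seed seed for any stochastic choices (kept for reproducibility;
#'   the engine itself is deterministic).
#' @return list of settings.
#' @export
reg_control <- function(metric = c("nmi", "ssd"), nbins = 32,
                        stages = c("rigid", "affine", "bspline"),
                        levels = c(4, 2), grid_spacing_mm = c(24, 12),
                        steps_mm = list(c(4, 2, 1), c(2, 1, 0.5)),
                        passes = 3, rigid_maxit = 200, affine_maxit = 150,
                        mask_dilate_mm = 8, sample_stride = 1,
                        smooth_factor = 1, sync_passes = 40,
                        bending_lambda = 0.02, axes = c(TRUE, TRUE, TRUE),
                        rotations = TRUE, inverse_tolerance_mm = 0.1,
                        seed = 1L) {
  metric <- match.arg(metric)
  list(metric = metric, nbins = nbins, stages = stages, levels = levels,
       grid_spacing_mm = grid_spacing_mm, steps_mm = steps_mm,
       passes = passes, rigid_maxit = rigid_maxit,
       affine_maxit = affine_maxit, mask_dilate_mm = mask_dilate_mm,
       sample_stride = sample_stride, smooth_factor = smooth_factor,
       sync_passes = sync_passes, bending_lambda = bending_lambda,
       axes = axes, rotations = rotations,
       inverse_tolerance_mm = inverse_tolerance_mm, seed = seed)
}

# downsample a volume in-plane by integer factor (z untouched: section
# spacing is already coarse)
downsample_level <- function(vol, factor, smooth_factor = 1) {
  if (factor <= 1) return(vol)
  # anti-aliased pyramid: Gaussian blur proportional to the decimation both
  # stabilizes the metric and widens its capture basins for thin structures
  sig <- c(vol$spacing[1] * factor, vol$spacing[2] * factor, 0) * smooth_factor
  sm <- cpp_gauss_smooth(vol$voxels, vol$spacing, sig)
  resample_volume(image_volume(sm, vol$spacing, vol$origin), NULL,
                  target_spacing = vol$spacing * c(factor, factor, 1))$volume
}

# metric sample points/bins for a fixed volume, optionally masked
metric_samples <- function(fixed, nbins, mask_arr = NULL, stride = 1) {
  d <- dim(fixed$voxels)
  keep <- array(TRUE, d)
  if (!is.null(mask_arr)) keep <- keep & mask_arr
  if (stride > 1) {
    sel <- array(FALSE, d)
    sel[seq(1, d[1], stride), seq(1, d[2], stride), ] <- TRUE
    keep <- keep & sel
  }
  idx <- which_voxels(keep)
  vals <- fixed$voxels[idx]
  rng <- range(fixed$voxels)
  bins <- pmin(nbins - 1L,
               pmax(0L, as.integer(floor((vals - rng[1]) /
                                         max(rng[2] - rng[1], 1e-12) *
                                         (nbins - 1L) + 0.5))))
  list(pts = voxel_to_physical(idx, fixed$spacing, fixed$origin),
       bins = bins, vals = vals)
}

rigid_matrix <- function(par, center) {
  cx <- cos(par[4]); sx <- sin(par[4])
  cy <- cos(par[5]); sy <- sin(par[5])
  cz <- cos(par[6]); sz <- sin(par[6])
  Rx <- matrix(c(1, 0, 0, 0, cx, -sx, 0, sx, cx), 3, byrow = TRUE)
  Ry <- matrix(c(cy, 0, sy, 0, 1, 0, -sy, 0, cy), 3, byrow = TRUE)
  Rz <- matrix(c(cz, -sz, 0, sz, cz, 0, 0, 0, 1), 3, byrow = TRUE)
  R <- Rz %*% Ry %*% Rx
  list(A = R, t = par[1:3] + center - R %*% center)
}

# background fill for out-of-volume samples: the grid-corner consensus is the
# natural background estimate (using the intensity minimum would declare
# 'inside wall' outside the volume for signed-distance channels)
background_fill <- function(vol) {
  d <- dim(vol$voxels)
  median(vol$voxels[cbind(c(1, d[1], 1, d[1], 1, d[1], 1, d[1]),
                          c(1, 1, d[2], d[2], 1, 1, d[2], d[2]),
                          c(1, 1, 1, 1, d[3], d[3], d[3], d[3]))])
}

metric_value <- function(samp, moving, A, t, coef, go, gs, control, mrng,
                         fill) {
  if (control$metric == "nmi") {
    cpp_nmi(samp$bins, samp$pts, moving$voxels, moving$spacing, moving$origin,
            A, as.numeric(t), coef, go, gs, control$nbins, mrng[1], mrng[2],
            fill)
  } else {
    warped <- cpp_sample(moving$voxels, moving$spacing, moving$origin,
                         cpp_apply_transform(A, as.numeric(t), coef, go, gs,
                                             samp$pts),
                         fill, FALSE)
    -mean((warped - samp$vals)^2)
  }
}

#' Register a moving volume onto a fixed volume
#'
#' Staged rigid, affine and cubic b-spline free-form registration maximizing
#' normalized mutual information (or minimizing SSD), multi-resolution, with
#' a deterministic greedy coordinate-descent optimizer for the b-spline
#' stage. Returns the transform `G` mapping fixed-space physical points into
#' moving-space physical points (the resampling pull-back: the moving volume
#' aligned onto the fixed grid is `moving(G(x))`).
#'
#' @param fixed,moving [image_volume()]s on compatible physical domains.
#' @param control a [reg_control()].
#' @param fixed_mask optional logical array over the fixed grid restricting
#'   the metric region (before dilation).
#' @param init_translation initial translation of the transform (mm),
#'   typically the moving-minus-fixed ROI centroid difference (center-of-mass
#'   initializer).
#' @return list with `transform` (a [composite_transform()]), and
#'   `diagnostics` (per-stage metric values and a `converged` flag).
#' @export
register_volumes <- function(fixed, moving, control = reg_control(),
                             fixed_mask = NULL, init_translation = c(0, 0, 0)) {
  mrng <- range(moving$voxels)
  fill <- background_fill(moving)
  d <- dim(fixed$voxels)
  center <- fixed$origin + (d - 1) * fixed$spacing / 2
  A <- diag(3)
  tt <- as.numeric(init_translation)
  diag_log <- list()

  mask_full <- NULL
  if (!is.null(control$mask_dilate_mm) && !is.null(fixed_mask)) {
    sq <- cpp_sq_edt(as.numeric_array(fixed_mask), fixed$spacing)
    mask_full <- array(sq <= control$mask_dilate_mm^2, d)
  } else if (!is.null(fixed_mask)) {
    mask_full <- fixed_mask
  }

  coef <- NULL
  go <- c(0, 0, 0)
  gs <- c(1, 1, 1)

  for (li in seq_along(control$levels)) {
    f <- control$levels[li]
    fx <- downsample_level(fixed, f, control$smooth_factor)
    mv <- downsample_level(moving, f, control$smooth_factor)
    mk <- NULL
    if (!is.null(mask_full)) {
      mk <- array(cpp_warp_volume(as.numeric_array(mask_full), fixed$spacing,
                                  fixed$origin, diag(3), c(0, 0, 0), NULL,
                                  c(0, 0, 0), c(1, 1, 1), dim(fx$voxels),
                                  fx$spacing, fx$origin, 0, TRUE) > 0,
                  dim(fx$voxels))
      if (sum(mk) < 50) mk <- NULL
    }
    samp <- metric_samples(fx, control$nbins, mk, control$sample_stride)

    # global stages refine at every pyramid level (coarse finds the basin,
    # fine sharpens the optimum); scales shrink with the level
    lscale <- 1 / li
    if ("rigid" %in% control$stages && !is.null(coef)) {
      # translation-only re-refinement: once the deformable stage has
      # aligned the structures, the weakly constrained global offsets
      # (especially along near-symmetry axes) can be re-estimated without
      # the bias they pick up while shapes still mismatch
      cf <- as.numeric_array(coef)
      free3 <- which(control$axes)
      obj <- function(parf) {
        par <- numeric(3)
        par[free3] <- parf
        -metric_value(samp, mv, A, tt + par, cf, go, gs, control, mrng, fill)
      }
      opt <- stats::optim(rep(0, length(free3)), obj, method = "Nelder-Mead",
                          control = list(maxit = 100,
                                         parscale = rep(2, length(free3)) *
                                           lscale))
      par <- numeric(3)
      par[free3] <- opt$par
      tt <- tt + par
      diag_log[[paste0("trans_refine_level", li)]] <- -opt$value
    }
    if ("rigid" %in% control$stages && is.null(coef)) {
      A0 <- A
      t0 <- tt
      # with the third axis frozen only in-plane displacements and the
      # in-plane rotation remain free
      free6 <- if (control$axes[3]) 1:3 else 1:2
      if (control$rotations)
        free6 <- c(free6, if (control$axes[3]) 4:6 else 6)
      obj <- function(parf) {
        par <- numeric(6)
        par[free6] <- parf
        rt <- rigid_matrix(par, center)
        -metric_value(samp, mv, rt$A %*% A0, rt$A %*% t0 + rt$t, NULL, go, gs,
                      control, mrng, fill)
      }
      opt <- stats::optim(rep(0, length(free6)), obj, method = "Nelder-Mead",
                          control = list(maxit = control$rigid_maxit,
                                         parscale = c(5, 5, 5, 0.1, 0.1, 0.1)[free6] *
                                           lscale))
      par <- numeric(6)
      par[free6] <- opt$par
      rt <- rigid_matrix(par, center)
      A <- rt$A %*% A0
      tt <- as.numeric(rt$A %*% t0 + rt$t)
      diag_log[[paste0("rigid_level", li)]] <- -opt$value
    }
    if ("affine" %in% control$stages && is.null(coef)) {
      free12 <- if (control$axes[3]) 1:12 else c(1, 2, 4, 5, 10, 11)
      obj <- function(parf) {
        par <- numeric(12)
        par[free12] <- parf
        Ad <- A + matrix(par[1:9], 3, 3)
        td <- tt + par[10:12]
        -metric_value(samp, mv, Ad, td, NULL, go, gs, control, mrng, fill)
      }
      opt <- stats::optim(rep(0, length(free12)), obj, method = "Nelder-Mead",
                          control = list(maxit = control$affine_maxit,
                                         parscale = c(rep(0.05, 9), rep(2, 3))[free12] *
                                           lscale))
      par <- numeric(12)
      par[free12] <- opt$par
      A <- A + matrix(par[1:9], 3, 3)
      tt <- tt + par[10:12]
      diag_log[[paste0("affine_level", li)]] <- -opt$value
    }

    if ("bspline" %in% control$stages) {
      h <- rep(control$grid_spacing_mm[min(li, length(control$grid_spacing_mm))], 3)
      dom_min <- fx$origin
      dom_max <- fx$origin + (dim(fx$voxels) - 1) * fx$spacing
      nc <- as.integer(ceiling((dom_max - dom_min) / h)) + 4L
      go_new <- dom_min - 2 * h
      coef_new <- array(0, dim = c(nc, 3))
      if (!is.null(coef)) {
        # resample previous level's displacement onto the new control grid
        # (control coefficients approximated by sampled displacements)
        cp <- as.matrix(expand.grid(x = go_new[1] + (seq_len(nc[1]) - 1) * h[1],
                                    y = go_new[2] + (seq_len(nc[2]) - 1) * h[2],
                                    z = go_new[3] + (seq_len(nc[3]) - 1) * h[3]))
        u <- cpp_ffd_disp(as.numeric_array(coef), go, gs, cp)
        for (dd in 1:3) coef_new[, , , dd] <- array(u[, dd], nc)
      }
      steps <- control$steps_mm[[min(li, length(control$steps_mm))]]
      res <- cpp_ffd_optimize(samp$bins, samp$vals, samp$pts, mv$voxels,
                              mv$spacing, mv$origin, A, tt, coef_new, go_new,
                              h, steps, control$passes, control$sync_passes,
                              control$nbins, mrng[1], mrng[2], fill,
                              if (control$metric == "nmi") 0L else 1L,
                              control$bending_lambda,
                              as.integer(control$axes))
      coef <- res$coef
      go <- go_new
      gs <- h
      diag_log[[paste0("bspline_level", li)]] <-
        c(initial = res$metric_initial, final = res$metric_final)
    }
  }

  if ("rigid" %in% control$stages && "bspline" %in% control$stages &&
      !is.null(coef)) {
    cf <- as.numeric_array(coef)
    free3 <- which(control$axes)
    obj <- function(parf) {
      par <- numeric(3)
      par[free3] <- parf
      -metric_value(samp, mv, A, tt + par, cf, go, gs, control, mrng, fill)
    }
    opt <- stats::optim(rep(0, length(free3)), obj, method = "Nelder-Mead",
                        control = list(maxit = 100,
                                       parscale = rep(1, length(free3))))
    par <- numeric(3)
    par[free3] <- opt$par
    tt <- tt + par
    diag_log$trans_refine_final <- -opt$value
  }

  tr <- composite_transform(A, tt, coef, go, gs)
  # convergence check at the finest level actually optimized: the staged
  # optimizers only ever accept improvements, so a final similarity below
  # its identity-transform value signals divergence
  final_metric <- metric_value(samp, mv, tr$A, tr$t,
                               if (is.null(coef)) NULL else as.numeric_array(coef),
                               go, gs, control, mrng, fill)
  id_metric <- metric_value(samp, mv, diag(3), c(0, 0, 0), NULL, go, gs,
                            control, mrng, fill)
  diag_log$metric_identity <- id_metric
  diag_log$metric_final <- final_metric
  diag_log$converged <- final_metric >= id_metric - 1e-9
  list(transform = tr, diagnostics = diag_log)
}

#' Transform pair container
#'
#' Forward composite transform plus its dense inverse over the atlas grid,
#' with the measured inverse-consistency error.
#' @keywords internal
transform_pair <- function(forward, inverse, inverse_consistency_error,
                           flagged, diagnostics, grid) {
  structure(list(forward = forward, inverse = inverse,
                 inverse_consistency_error = inverse_consistency_error,
                 flagged = flagged, diagnostics = diagnostics, grid = grid),
            class = "transform_pair")
}

#' Register the atlas to a patient and return the transform pair
#'
#' Registers the atlas template (moving) onto the preprocessed patient volume
#' (fixed) through staged rigid/affine/b-spline alignment, yielding `G`
#' (patient space to atlas space), then inverts `G` over the atlas grid so
#' the patient can be mapped into atlas space. The inverse-consistency error
#' `max |G(G^-1(x)) - x|` over the wall ROI is recorded and the pair is
#' flagged when it exceeds the configured tolerance.
#'
#' @param atlas an [build_atlas()] result (or a list with a `template`
#'   [image_volume()]).
#' @param patient preprocessed patient [image_volume()] on the atlas grid
#'   shape.
#' @param mask the patient [annotation_mask()].
#' @param control a [reg_control()].
#' @param channel `"intensity"` (NMI on the images, the default) or
#'   `"structural"` (SSD on smoothed wall signed-distance transforms; robust
#'   when the atlas and patient appearances are uncorrelated, as with
#'   synthetic phantoms).
#' @return a `transform_pair` with elements `forward`, `inverse` (list of
#'   dense inverse points over the atlas grid), `inverse_consistency_error`
#'   (mm, max over ROI), `flagged`, and `diagnostics`.
#' @export
register_atlas_to_patient <- function(atlas, patient, mask,
                                      control = reg_control(),
                                      channel = c("intensity", "structural")) {
  channel <- match.arg(channel)
  stopifnot_same_grid(patient, mask)
  if (!identical(dim(patient$voxels), dim(atlas$template$voxels)))
    stop("patient must be preprocessed to the atlas grid shape ",
         "(see center_crop_to_roi)")
  wall <- mask$labels == LABEL_WALL
  # center-of-mass initialization: moving minus fixed wall centroid
  fc <- label_centroid(wall, patient$spacing, patient$origin)
  mc <- label_centroid(atlas$wall_prob >= 0.5, atlas$template$spacing,
                       atlas$template$origin)
  if (channel == "structural") {
    # drive the alignment on smoothed signed-distance transforms of the wall
    # (structure, not appearance); SSD is the natural metric on this channel
    fixed_chan <- signed_distance_wall(mask)
    atlas_mask <- annotation_mask(
      array(ifelse(atlas$wall_prob >= 0.5, LABEL_WALL, LABEL_BACKGROUND),
            dim(atlas$template$voxels)),
      atlas$template$spacing, atlas$template$origin)
    moving_chan <- signed_distance_wall(atlas_mask)
    control$metric <- "ssd"
  } else {
    fixed_chan <- patient
    moving_chan <- atlas$template
  }
  reg <- register_volumes(fixed_chan, moving_chan, control,
                          fixed_mask = wall, init_translation = mc - fc)
  if (!reg$diagnostics$converged)
    stop("registration failure: similarity decreased below its identity ",
         "value (NMI ", signif(reg$diagnostics$metric_final, 5), " < ",
         signif(reg$diagnostics$metric_identity, 5), ")")
  # invert over the atlas grid; ROI for the consistency check = dilated wall
  d <- dim(atlas$template$voxels)
  allroi <- array(TRUE, d)
  inv <- invert_transform(reg$transform, allroi, atlas$template$spacing,
                          atlas$template$origin,
                          tolerance_mm = control$inverse_tolerance_mm)
  ice <- if (length(inv$residual_mm)) max(inv$residual_mm) else Inf
  flagged <- ice > control$inverse_tolerance_mm
  if (flagged)
    warning(sprintf("inverse-consistency error %.3g mm exceeds tolerance %.3g mm",
                    ice, control$inverse_tolerance_mm))
  transform_pair(reg$transform, inv, ice, flagged, reg$diagnostics,
                 list(dim = d, spacing = atlas$template$spacing,
                      origin = atlas$template$origin))
}

#' @export
print.transform_pair <- function(x, ...) {
  cat(sprintf("<transform_pair> inverse-consistency %.4g mm%s\n",
              x$inverse_consistency_error,
              if (x$flagged) " (FLAGGED)" else ""))
  invisible(x)
}

#' Extract the per-voxel displacement field in atlas space
#'
#' For every atlas-grid voxel carrying the patient's wall label (after
#' mapping the patient annotation into atlas space), the displacement vector
#' is the patient-space position of that material point minus its atlas-space
#' position, in mm. Outward tumor growth therefore produces vectors pointing
#' away from the lumen and inward displacement vectors pointing toward it.
#'
#' @param pair a `transform_pair` from [register_atlas_to_patient()].
#' @param mask the patient [annotation_mask()] (patient grid).
#' @return a [deformation_field()] over the atlas grid; the warped patient
#'   mask in atlas space is attached as attribute `"warped_mask"`.
#' @export
extract_displacements <- function(pair, mask) {
  g <- pair$grid
  d <- g$dim
  # dense inverse points were computed over the whole grid in order
  full_idx <- pair$inverse$roi_index
  if (nrow(full_idx) == 0L) stop("empty ROI: transform inversion kept no voxels")
  pts_atlas <- voxel_to_physical(full_idx, g$spacing, g$origin)
  pts_patient <- pair$inverse$points
  labels <- cpp_sample(as.numeric_array(mask$labels), mask$spacing, mask$origin,
                       pts_patient, LABEL_BACKGROUND, TRUE)
  warped <- array(LABEL_BACKGROUND, d)
  warped[full_idx] <- as.integer(round(labels))
  wall <- warped == LABEL_WALL
  if (!any(wall)) stop("empty ROI: no wall voxels map into atlas space")
  vecs <- array(0, dim = c(d, 3))
  disp <- pts_patient - pts_atlas
  keep <- wall[full_idx]
  kidx <- full_idx[keep, , drop = FALSE]
  vecs[cbind(kidx, 1)] <- disp[keep, 1]
  vecs[cbind(kidx, 2)] <- disp[keep, 2]
  vecs[cbind(kidx, 3)] <- disp[keep, 3]
  field <- deformation_field(vecs, roi = wall, spacing = g$spacing,
                             origin = g$origin)
  attr(field, "warped_mask") <- annotation_mask(warped, g$spacing, g$origin,
                                                mask$provenance)
  field
}
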