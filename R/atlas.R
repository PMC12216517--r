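# Atlas construction: subjects are aligned into a canonical space through the
# staged registration engine and averaged into a template with per-voxel
# wall/lumen frequency maps. Because the atlas is *structural* (wall and
# lumen anatomy, not intensity appearance), registration during construction
# is driven on smoothed signed-distance transforms of the wall masks with an
# SSD metric; this is configurable back to raw-intensity NMI.

# signed distance (mm) to the wall surface: negative inside the wall
signed_distance_wall <- function(mask) {
  wall <- mask$labels == LABEL_WALL
  dout <- sqrt(cpp_sq_edt(as.numeric_array(wall), mask$spacing))
  din <- sqrt(cpp_sq_edt(as.numeric_array(!wall), mask$spacing))
  sdt <- dout - din
  # soft clamp keeps the far field from dominating SSD
  image_volume(tanh(array(sdt, dim(wall)) / 10) * 10, mask$spacing,
               mask$origin)
}

#' Build a canonical non-diseased organ atlas
#'
#' Aligns a cohort of wall/lumen-annotated volumes into a canonical space and
#' averages them: the first iteration registers every subject to the
#' median-wall-volume subject, later iterations to the evolving mean template
#' (a groupwise surrogate). The atlas records the mean intensity template and
#' per-voxel wall/lumen frequency maps. Iteration stops when the mean
#' absolute template change drops below `tolerance` of the intensity range or
#' after `max_iters` iterations.
#'
#' @param cohort list of `list(volume =, mask =)` pairs, preprocessed to a
#'   common spacing and shape.
#' @param reference_strategy `"median"` (median wall volume) or `"first"`.
#' @param max_iters maximum template refinement iterations (default 5).
#' @param tolerance relative mean template change for convergence.
#' @param control a [reg_control()]; default drives the alignment on wall
#'   signed-distance channels with an SSD metric.
#' @param channel `"sdt"` (structural, default) or `"intensity"`.
#' @return object of class `organ_atlas`: `template` ([image_volume()]),
#'   `wall_prob`, `lumen_prob` (arrays in `[0,1]`), `cohort_size`,
#'   `build_log`.
#' @export
build_atlas <- function(cohort, reference_strategy = c("median", "first"),
                        max_iters = 5, tolerance = 1e-3,
                        control = reg_control(metric = "ssd"),
                        channel = c("sdt", "intensity")) {
  reference_strategy <- match.arg(reference_strategy)
  channel <- match.arg(channel)
  if (length(cohort) < 2) stop("atlas cohort must have >= 2 subjects")
  shp <- dim(cohort[[1]]$volume$voxels)
  sp <- cohort[[1]]$volume$spacing
  for (s in cohort) {
    if (!identical(dim(s$volume$voxels), shp) ||
        max(abs(s$volume$spacing - sp)) > 1e-6)
      stop("all cohort volumes must share spacing and shape ",
           "(preprocess first)")
    stopifnot_same_grid(s$volume, s$mask)
  }

  wv <- vapply(cohort, function(s) wall_volume(s$mask), numeric(1))
  ref_i <- if (reference_strategy == "median")
    order(wv)[ceiling(length(wv) / 2)] else 1L
  ref_vol <- cohort[[ref_i]]$volume
  ref_chan <- if (channel == "sdt") signed_distance_wall(cohort[[ref_i]]$mask)
              else ref_vol
  ref_wall_prob <- NULL

  build_log <- list(reference = ref_i, iterations = list())
  excluded <- logical(length(cohort))
  template <- NULL

  for (iter in seq_len(max_iters)) {
    warped_vol <- vector("list", length(cohort))
    warped_wall <- vector("list", length(cohort))
    warped_lumen <- vector("list", length(cohort))
    iter_log <- list()
    for (i in seq_along(cohort)) {
      if (excluded[i]) next
      subj_chan <- if (channel == "sdt")
        signed_distance_wall(cohort[[i]]$mask) else cohort[[i]]$volume
      ref_wall <- if (is.null(ref_wall_prob))
        cohort[[ref_i]]$mask$labels == LABEL_WALL else ref_wall_prob >= 0.5
      init_t <- label_centroid(cohort[[i]]$mask$labels == LABEL_WALL, sp,
                               cohort[[i]]$mask$origin) -
        label_centroid(ref_wall, sp, ref_vol$origin)
      reg <- tryCatch(
        register_volumes(ref_chan, subj_chan, control, fixed_mask = ref_wall,
                         init_translation = init_t),
        error = function(e) NULL)
      if (is.null(reg) || !reg$diagnostics$converged) {
        warning("subject ", i, " failed registration convergence; excluded")
        excluded[i] <- TRUE
        next
      }
      tr <- reg$transform
      cf <- if (is.null(tr$coef)) NULL else as.numeric_array(tr$coef)
      warp1 <- function(arr, src, nearest, fill)
        array(cpp_warp_volume(as.numeric_array(arr), src$spacing, src$origin, tr$A,
                              tr$t, cf, tr$grid_origin, tr$grid_spacing, shp,
                              sp, ref_vol$origin, fill, nearest), shp)
      warped_vol[[i]] <- warp1(cohort[[i]]$volume$voxels, cohort[[i]]$volume,
                               FALSE, 0)
      warped_wall[[i]] <- warp1(cohort[[i]]$mask$labels == LABEL_WALL,
                                cohort[[i]]$mask, TRUE, 0)
      warped_lumen[[i]] <- warp1(cohort[[i]]$mask$labels == LABEL_LUMEN,
                                 cohort[[i]]$mask, TRUE, 0)
      iter_log[[length(iter_log) + 1L]] <-
        list(subject = i, metric = reg$diagnostics$metric_final)
    }
    kept <- which(!excluded & !vapply(warped_vol, is.null, logical(1)))
    if (length(kept) < 2) stop("fewer than 2 subjects survived registration")
    new_template <- Reduce(`+`, warped_vol[kept]) / length(kept)
    wall_prob <- Reduce(`+`, warped_wall[kept]) / length(kept)
    lumen_prob <- Reduce(`+`, warped_lumen[kept]) / length(kept)
    build_log$iterations[[iter]] <- iter_log
    if (!is.null(template)) {
      rng <- max(diff(range(template)), 1e-12)
      delta <- mean(abs(new_template - template)) / rng
      template <- new_template
      build_log$template_change <- c(build_log$template_change, delta)
      if (delta < tolerance) break
    } else template <- new_template
    # subsequent iterations target the evolving mean template
    ref_wall_prob <- wall_prob
    ref_chan <- if (channel == "sdt") {
      m <- annotation_mask(array(ifelse(wall_prob >= 0.5, LABEL_WALL,
                                        LABEL_BACKGROUND), shp),
                           sp, ref_vol$origin)
      signed_distance_wall(m)
    } else image_volume(template, sp, ref_vol$origin)
    if (iter == max_iters) break
  }

  # De-bias the canonical space: per-subject registration drift (especially
  # along weakly constrained axes) accumulates into the average, displacing
  # the template from where the cohort actually sits. Anchor the atlas by
  # translating it so its wall-probability centroid coincides with the
  # cohort-mean wall centroid (the unbiased consensus position).
  kept_idx <- which(!excluded)
  target_c <- colMeans(do.call(rbind, lapply(cohort[kept_idx], function(s)
    label_centroid(s$mask$labels == LABEL_WALL, sp, s$mask$origin))))
  widx <- which_voxels(wall_prob > 0)
  w <- wall_prob[widx]
  cur_c <- colSums(voxel_to_physical(widx, sp, ref_vol$origin) * w) / sum(w)
  shift <- cur_c - target_c
  if (sqrt(sum(shift^2)) > 1e-3) {
    recenter <- function(arr, fill)
      array(cpp_warp_volume(as.numeric_array(arr), sp, ref_vol$origin,
                            diag(3), shift, NULL, c(0, 0, 0), c(1, 1, 1),
                            shp, sp, ref_vol$origin, fill, FALSE), shp)
    template <- recenter(template, median(template))
    wall_prob <- recenter(wall_prob, 0)
    wall_prob[wall_prob < 0] <- 0
    wall_prob[wall_prob > 1] <- 1
    lumen_prob <- recenter(lumen_prob, 0)
    lumen_prob[lumen_prob < 0] <- 0
    lumen_prob[lumen_prob > 1] <- 1
    build_log$recenter_shift_mm <- shift
  }

  structure(list(template = image_volume(template, sp, ref_vol$origin),
                 wall_prob = wall_prob, lumen_prob = lumen_prob,
                 cohort_size = length(which(!excluded)),
                 excluded = which(excluded), build_log = build_log),
            class = "organ_atlas")
}

#' @export
print.organ_atlas <- function(x, ...) {
  d <- dim(x$template$voxels)
  cat(sprintf("<organ_atlas> N = %d, %d x %d x %d grid, wall_prob in [%.2f, %.2f]\n",
              x$cohort_size, d[1], d[2], d[3], min(x$wall_prob),
              max(x$wall_prob)))
  invisible(x)
}

dice_overlap <- function(a, b) {
  inter <- sum(a & b)
  denom <- sum(a) + sum(b)
  if (denom == 0) return(1)
  2 * inter / denom
}

#' Evaluate atlas construction quality
#'
#' Re-registers each cohort subject to the atlas template and reports the
#' Dice overlap between the aligned subject wall mask and the atlas wall
#' probability map thresholded at 0.5.
#'
#' @param atlas an `organ_atlas`.
#' @param cohort the cohort used to build it.
#' @param control a [reg_control()].
#' @param channel `"sdt"` or `"intensity"`, as in [build_atlas()].
#' @return list with per-subject `dice`, `mean` and `min`.
#' @export
atlas_quality <- function(atlas, cohort, control = reg_control(metric = "ssd"),
                          channel = c("sdt", "intensity")) {
  channel <- match.arg(channel)
  shp <- dim(atlas$template$voxels)
  sp <- atlas$template$spacing
  atlas_wall <- atlas$wall_prob >= 0.5
  ref_chan <- if (channel == "sdt") {
    m <- annotation_mask(array(ifelse(atlas_wall, LABEL_WALL,
                                      LABEL_BACKGROUND), shp), sp,
                         atlas$template$origin)
    signed_distance_wall(m)
  } else atlas$template
  dice <- vapply(cohort, function(s) {
    subj_chan <- if (channel == "sdt") signed_distance_wall(s$mask)
                 else s$volume
    init_t <- label_centroid(s$mask$labels == LABEL_WALL, sp, s$mask$origin) -
      label_centroid(atlas_wall, sp, atlas$template$origin)
    reg <- register_volumes(ref_chan, subj_chan, control,
                            fixed_mask = atlas_wall,
                            init_translation = init_t)
    tr <- reg$transform
    w <- array(cpp_warp_volume(as.numeric_array(s$mask$labels == LABEL_WALL),
                               s$mask$spacing, s$mask$origin, tr$A, tr$t,
                               if (is.null(tr$coef)) NULL
                               else as.numeric_array(tr$coef),
                               tr$grid_origin, tr$grid_spacing, shp, sp,
                               atlas$template$origin, 0, TRUE), shp)
    dice_overlap(w > 0, atlas_wall)
  }, numeric(1))
  list(dice = dice, mean = mean(dice), min = min(dice))
}

#' Save / load an atlas directory
#'
#' The atlas is written as a directory of NIfTI volumes
#' (`template.nii.gz`, `wall_prob.nii.gz`, `lumen_prob.nii.gz`) plus
#' `meta.json`.
#'
#' @param atlas an `organ_atlas`.
#' @param dir directory path.
#' @return (invisibly) `dir`, or the loaded `organ_atlas`.
#' @export
save_atlas <- function(atlas, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_volume_nifti(atlas$template, file.path(dir, "template.nii.gz"))
  sp <- atlas$template$spacing
  og <- atlas$template$origin
  write_nifti_raw(atlas$wall_prob, file.path(dir, "wall_prob.nii.gz"), sp, og, 16L)
  write_nifti_raw(atlas$lumen_prob, file.path(dir, "lumen_prob.nii.gz"), sp, og, 16L)
  jsonlite::write_json(list(cohort_size = atlas$cohort_size,
                            spacing = sp, origin = og),
                       file.path(dir, "meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' @rdname save_atlas
#' @export
load_atlas <- function(dir) {
  template <- read_volume_nifti(file.path(dir, "template.nii.gz"))
  wp <- read_nifti_raw(file.path(dir, "wall_prob.nii.gz"))$data
  lp <- read_nifti_raw(file.path(dir, "lumen_prob.nii.gz"))$data
  meta <- jsonlite::read_json(file.path(dir, "meta.json"), simplifyVector = TRUE)
  structure(list(template = template, wall_prob = wp, lumen_prob = lp,
                 cohort_size = meta$cohort_size, excluded = integer(0),
                 build_log = list()),
            class = "organ_atlas")
}
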