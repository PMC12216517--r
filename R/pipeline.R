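# End-to-end convenience layer: phantom cohort -> atlas -> registration ->
# StODeO + texture feature table, ready for the ML and unsupervised stages.

#' Extract StODeO and texture features for one patient
#'
#' Preprocesses the patient to the atlas grid (resample + center/crop),
#' registers the atlas, extracts the atlas-space displacement field, and
#' computes the StODeO descriptor together with the texture bank on the
#' analysis region.
#'
#' @param atlas an `organ_atlas`.
#' @param volume patient [image_volume()].
#' @param mask patient [annotation_mask()].
#' @param control a [reg_control()].
#' @param region_mode analysis region mode.
#' @param texture logical: also extract the texture bank.
#' @param channel registration channel, see [register_atlas_to_patient()].
#' @return one-row data.frame of named features (plus `wall_volume`).
#' @export
extract_patient_features <- function(atlas, volume, mask,
                                     control = reg_control(),
                                     region_mode = "single_section",
                                     texture = TRUE,
                                     channel = c("intensity", "structural")) {
  channel <- match.arg(channel)
  sp <- atlas$template$spacing
  if (max(abs(volume$spacing - sp)) > 1e-6) {
    rs <- resample_volume(volume, mask, sp)
    volume <- rs$volume
    mask <- rs$mask
  }
  shp <- dim(atlas$template$voxels)
  if (!identical(dim(volume$voxels), shp)) {
    cc <- center_crop_to_roi(volume, mask, shp)
    volume <- cc$volume
    mask <- cc$mask
  }
  pair <- register_atlas_to_patient(atlas, volume, mask, control, channel)
  field <- extract_displacements(pair, mask)
  wmask <- attr(field, "warped_mask")
  desc <- compute_stodeo(field, wmask, region_mode)
  row <- c(as.list(desc$f_m), as.list(desc$f_o),
           list(wall_volume = wall_volume(mask)))
  if (texture) {
    tx <- extract_texture_features(volume, mask, region_mode)
    row <- c(row, as.list(tx))
  }
  as.data.frame(row, check.names = FALSE)
}

#' Run a complete phantom study
#'
#' Generates a healthy (undeformed) tube cohort and builds the non-diseased
#' atlas from it, then generates a labeled deformed cohort
#' ([make_cohort()]), runs every phantom through registration and feature
#' extraction, and returns the assembled feature table (features + metadata +
#' wall volume), ready for [run_cv()], [consensus_cluster()] and
#' [spearman_fdr_map()].
#'
#' @param n cohort size.
#' @param seed integer seed driving every stochastic component.
#' @param n_atlas healthy subjects used to build the atlas.
#' @param class_mix responder fraction (study composition 0.36).
#' @param region_mode analysis region mode.
#' @param control registration settings; the default favors speed at the
#'   phantom's effect sizes.
#' @param texture logical: include the texture bank.
#' @param channel registration channel; the phantom default is
#'   `"structural"` (atlas and phantom appearances are uncorrelated, so the
#'   wall signed-distance channel carries the alignment signal).
#' @param atlas optionally, a prebuilt atlas to reuse.
#' @param cohort optionally, a prebuilt [make_cohort()] result.
#' @param ... passed to [make_cohort()].
#' @return list with `table` (feature data.frame), `atlas`, `manifest`.
#' @export
phantom_study <- function(n = 60, seed = 1L, n_atlas = 3, class_mix = 0.36,
                          region_mode = "single_section",
                          control = reg_control(stages = c("rigid", "bspline"),
                                                steps_mm = list(c(6, 4, 2),
                                                                c(2, 1, 0.5)),
                                                passes = 2,
                                                bending_lambda = 0.01,
                                                axes = c(TRUE, TRUE, FALSE),
                                                rotations = FALSE),
                          texture = TRUE, channel = "structural",
                          atlas = NULL, cohort = NULL, ...) {
  if (is.null(atlas)) {
    healthy <- lapply(seq_len(n_atlas), function(i) {
      tube <- make_tube(tube_phantom_spec(seed = seed * 100L + i,
                                          noise_sd = 0.02))
      list(volume = tube$volume, mask = tube$mask)
    })
    atlas <- build_atlas(healthy, max_iters = 1,
                         control = reg_control(metric = "ssd",
                                               stages = c("rigid", "bspline"),
                                               levels = 4,
                                               grid_spacing_mm = 24,
                                               steps_mm = list(c(2, 1)),
                                               passes = 2,
                                               axes = c(TRUE, TRUE, FALSE),
                                               rotations = FALSE))
  }
  if (is.null(cohort)) cohort <- make_cohort(n, class_mix, seed, ...)
  rows <- vector("list", length(cohort$specs))
  for (i in seq_along(cohort$specs)) {
    tube <- make_tube(cohort$specs[[i]])
    rows[[i]] <- extract_patient_features(atlas, tube$volume, tube$mask,
                                          control, region_mode, texture,
                                          channel)
  }
  features <- do.call(rbind, rows)
  table <- cbind(cohort$manifest, features)
  list(table = table, atlas = atlas, manifest = cohort$manifest)
}
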