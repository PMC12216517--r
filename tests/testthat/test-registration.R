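test_that("transform inversion satisfies closed forms and the composition contract", {
  roi <- array(TRUE, c(12, 12, 4))
  sp <- c(1.5, 1.5, 4)

  # identity forward: identity inverse with zero residual
  tid <- composite_transform()
  inv <- invert_transform(tid, roi, sp, c(0, 0, 0))
  expect_lt(max(abs(inv$displacement)), 1e-12)
  expect_lt(max(inv$residual_mm), 1e-12)

  # pure translation: inverse is exactly -t
  tt <- composite_transform(diag(3), c(3, -2, 1))
  inv2 <- invert_transform(tt, roi, sp, c(0, 0, 0))
  expect_equal(unname(colMeans(inv2$displacement)), c(-3, 2, -1),
               tolerance = 1e-9)
  expect_equal(unname(apply(inv2$displacement, 2, sd)), c(0, 0, 0),
               tolerance = 1e-9)

  # random smooth b-spline forwards: |G(G^-1(x)) - x| <= 0.1 mm on >= 99%
  # of ROI voxels, checked by direct composition
  for (seed in 1:3) {
    tr <- random_bspline_transform(c(0, 0, 0), c(18, 18, 16),
                                   grid_spacing = c(10, 10, 10),
                                   relative_amplitude = 0.15, seed = seed)
    inv3 <- invert_transform(tr, roi, sp, c(0, 0, 0), tolerance_mm = 0.1)
    x0 <- sweep(inv3$roi_index - 1, 2, sp, "*")
    resid <- sqrt(rowSums((apply_transform(tr, inv3$points) - x0)^2))
    expect_gte(mean(resid <= 0.1), 0.99)
  }
})

test_that("folded (negative-Jacobian) voxels are excluded and counted", {
  # an aggressive random field folds somewhere; those voxels must be dropped
  tr <- random_bspline_transform(c(0, 0, 0), c(20, 20, 8),
                                 grid_spacing = c(6, 6, 6),
                                 relative_amplitude = 0.9, seed = 4)
  roi <- array(TRUE, c(14, 14, 3))
  inv <- invert_transform(tr, roi, c(1.5, 1.5, 3), c(0, 0, 0))
  expect_gt(inv$n_folded, 0)
  expect_equal(nrow(inv$points) + inv$n_folded, sum(roi))
})

test_that("self-registration of the template yields a near-null field", {
  atlas <- small_atlas()
  tpl <- atlas$template
  selfmask <- annotation_mask(
    array(ifelse(atlas$wall_prob >= 0.5, 1L,
                 ifelse(atlas$lumen_prob >= 0.5, 2L, 0L)),
          dim(tpl$voxels)), tpl$spacing, tpl$origin)
  pair <- register_atlas_to_patient(atlas, tpl, selfmask, fast_control())
  fld <- extract_displacements(pair, selfmask)
  med <- median(magnitude_field(fld)$values)
  expect_lt(med, 0.5 * min(tpl$spacing))
  expect_false(pair$flagged)
})

test_that("a known in-plane translation is recovered within 10%", {
  atlas <- small_atlas()
  tpl <- atlas$template
  shift <- c(5, 3.5, 0)
  mover <- function(arr, nearest, fill)
    array(stodeo:::cpp_warp_volume(stodeo:::as.numeric_array(arr),
                                   tpl$spacing, tpl$origin + shift, diag(3),
                                   c(0, 0, 0), NULL, c(0, 0, 0), c(1, 1, 1),
                                   dim(tpl$voxels), tpl$spacing, tpl$origin,
                                   fill, nearest), dim(tpl$voxels))
  patient <- image_volume(mover(tpl$voxels, FALSE, 0.45), tpl$spacing,
                          tpl$origin)
  labs <- array(ifelse(atlas$wall_prob >= 0.5, 1L,
                       ifelse(atlas$lumen_prob >= 0.5, 2L, 0L)),
                dim(tpl$voxels))
  pmask <- annotation_mask(mover(labs, TRUE, 0), tpl$spacing, tpl$origin)
  pair <- register_atlas_to_patient(atlas, patient, pmask, fast_control())
  fld <- extract_displacements(pair, pmask)
  rec <- colMeans(stodeo:::field_roi_vectors(fld)$vectors)
  expect_lt(sqrt(sum((rec[1:2] - shift[1:2])^2)) / sqrt(sum(shift^2)), 0.10)
})

test_that("a planted smooth radial warp is recovered through the transform pair", {
  atlas <- small_atlas()
  tube <- make_tube(small_spec(deformation = "inward_radial", amplitude = 3,
                               noise_sd = 0.05, heterogeneity = 0.25,
                               seed = 33))
  pair <- register_atlas_to_patient(atlas, tube$volume, tube$mask,
                                    fast_control(), channel = "structural")
  fld <- extract_displacements(pair, tube$mask)
  rv <- stodeo:::field_roi_vectors(fld)
  gt <- tube$field
  gtv <- cbind(gt$vectors[, , , 1][rv$idx], gt$vectors[, , , 2][rv$idx],
               gt$vectors[, , , 3][rv$idx])
  gtm <- sqrt(rowSums(gtv^2))
  hi <- gtm > 1.5
  expect_gt(sum(hi), 100)
  cs <- rowSums(rv$vectors * gtv) / (sqrt(rowSums(rv$vectors^2)) * gtm)
  expect_gt(mean(cs[hi], na.rm = TRUE), 0.8)
  # field error within 25% of the peak amplitude
  rmse <- sqrt(mean(rowSums((rv$vectors[hi, ] - gtv[hi, ])^2)))
  expect_lt(rmse, 0.25 * max(gtm))
})

test_that("displacements are physical (mm), not voxel units", {
  # same analytic phantom at two spacings: planted fields agree in mm
  t1 <- make_tube(small_spec(deformation = "outward_radial", amplitude = 2,
                             seed = 40))
  t2 <- make_tube(tube_phantom_spec(shape = c(96, 96, 12),
                                    spacing = c(0.8, 0.8, 4),
                                    deformation = "outward_radial",
                                    amplitude = 2, seed = 40))
  m1 <- magnitude_field(t1$field)$values
  m2 <- magnitude_field(t2$field)$values
  expect_equal(median(m1), 2, tolerance = 1e-9)
  expect_equal(median(m2), 2, tolerance = 1e-9)
})

test_that("registration is reproducible for a fixed configuration", {
  atlas <- small_atlas()
  tube <- make_tube(small_spec(deformation = "mixed", amplitude = 3,
                               seed = 44))
  p1 <- register_atlas_to_patient(atlas, tube$volume, tube$mask,
                                  fast_control(), channel = "structural")
  p2 <- register_atlas_to_patient(atlas, tube$volume, tube$mask,
                                  fast_control(), channel = "structural")
  expect_identical(p1$forward$coef, p2$forward$coef)
  expect_identical(p1$inverse_consistency_error, p2$inverse_consistency_error)
})
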