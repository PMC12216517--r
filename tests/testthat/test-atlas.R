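test_that("a degenerate identical cohort reproduces its subject exactly", {
  tube <- make_tube(small_spec(seed = 60, noise_sd = 0))
  cohort <- list(list(volume = tube$volume, mask = tube$mask),
                 list(volume = tube$volume, mask = tube$mask),
                 list(volume = tube$volume, mask = tube$mask))
  atlas <- build_atlas(cohort, max_iters = 1, control = fast_control())
  expect_lt(mean(abs(atlas$template$voxels - tube$volume$voxels)), 0.02)
  expect_true(all(atlas$wall_prob %in% c(0, 1)))
  expect_true(all(atlas$wall_prob >= 0 & atlas$wall_prob <= 1))
  expect_true(all(atlas$lumen_prob >= 0 & atlas$lumen_prob <= 1))
  expect_equal(atlas$cohort_size, 3)

  q <- atlas_quality(atlas, cohort, control = fast_control())
  expect_gte(min(q$dice), 0.98)
})

test_that("dice overlap ranges over identical and disjoint masks", {
  a <- array(FALSE, c(6, 6, 2)); a[1:3, , ] <- TRUE
  b <- array(FALSE, c(6, 6, 2)); b[4:6, , ] <- TRUE
  expect_equal(stodeo:::dice_overlap(a, a), 1)
  expect_equal(stodeo:::dice_overlap(a, b), 0)
})

test_that("rigidly shifted copies align into a sharp wall consensus", {
  base <- make_tube(small_spec(seed = 61, noise_sd = 0.02))
  tpl <- base$volume
  shifted_subject <- function(shift) {
    mover <- function(arr, nearest, fill)
      array(stodeo:::cpp_warp_volume(stodeo:::as.numeric_array(arr),
                                     tpl$spacing, tpl$origin + shift, diag(3),
                                     c(0, 0, 0), NULL, c(0, 0, 0), c(1, 1, 1),
                                     dim(tpl$voxels), tpl$spacing, tpl$origin,
                                     fill, nearest), dim(tpl$voxels))
    list(volume = image_volume(mover(tpl$voxels, FALSE, 0.45), tpl$spacing,
                               tpl$origin),
         mask = annotation_mask(mover(base$mask$labels, TRUE, 0),
                                tpl$spacing, tpl$origin))
  }
  cohort <- list(shifted_subject(c(0, 0, 0)), shifted_subject(c(4, 2, 0)),
                 shifted_subject(c(-3, 3, 0)))
  atlas <- build_atlas(cohort, max_iters = 1, control = fast_control())
  # consensus sits at the mean shift; compare against the base annulus moved
  # there
  ref <- shifted_subject(c(1/3, 5/3, 0))$mask$labels == 1L
  hit <- atlas$wall_prob[ref]
  expect_gte(mean(hit >= 0.9), 0.75)
  q <- atlas_quality(atlas, cohort, control = fast_control())
  expect_gte(q$mean, 0.85)
})

test_that("two wall radii blend into ring-geometry probabilities", {
  t1 <- make_tube(small_spec(seed = 62, noise_sd = 0, taper = 0,
                             inner_radius = 8, outer_radius = 12))
  t2 <- make_tube(small_spec(seed = 63, noise_sd = 0, taper = 0,
                             inner_radius = 8, outer_radius = 14))
  cohort <- list(list(volume = t1$volume, mask = t1$mask),
                 list(volume = t2$volume, mask = t2$mask))
  # identity alignment suffices here; exercise the averaging semantics with
  # a rigid-only configuration
  atlas <- build_atlas(cohort, max_iters = 1,
                       control = fast_control(stages = "rigid"))
  d <- dim(t1$mask$labels)
  xs <- (seq_len(d[1]) - 1) * 1.2
  cx <- mean(range(xs))
  r <- sqrt(outer((xs - cx)^2, (xs - cx)^2, "+"))
  mid <- array(FALSE, d); mid[, , 6] <- r >= 9 & r < 11      # shared ring
  band <- array(FALSE, d); band[, , 6] <- r >= 12.5 & r < 13.5  # disagreement
  expect_gte(mean(atlas$wall_prob[mid]), 0.95)
  bp <- atlas$wall_prob[band]
  expect_true(mean(bp) > 0.2 && mean(bp) < 0.8)
})

test_that("atlas construction is deterministic and order-robust", {
  subs <- lapply(1:3, function(i) {
    tube <- make_tube(small_spec(seed = 70 + i, noise_sd = 0.02,
                                 inner_radius = 7.5 + 0.3 * i))
    list(volume = tube$volume, mask = tube$mask)
  })
  a1 <- build_atlas(subs, max_iters = 1, control = fast_control())
  a2 <- build_atlas(subs, max_iters = 1, control = fast_control())
  expect_identical(a1$wall_prob, a2$wall_prob)

  a3 <- build_atlas(subs[c(2, 3, 1)], max_iters = 1, control = fast_control())
  expect_lt(mean(abs(a1$wall_prob - a3$wall_prob)), 0.05)

  expect_error(build_atlas(subs[1]), ">= 2")
})

test_that("atlas directories round-trip through save and load", {
  atlas <- small_atlas()
  dir <- tempfile()
  save_atlas(atlas, dir)
  expect_true(all(file.exists(file.path(dir,
    c("template.nii.gz", "wall_prob.nii.gz", "lumen_prob.nii.gz",
      "meta.json")))))
  back <- load_atlas(dir)
  expect_equal(back$cohort_size, atlas$cohort_size)
  expect_lt(max(abs(back$template$voxels - atlas$template$voxels)), 1e-4)
  expect_lt(max(abs(back$wall_prob - atlas$wall_prob)), 1e-4)
  unlink(dir, recursive = TRUE)
})
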