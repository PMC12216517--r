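test_that("undeformed tube matches analytic annulus geometry with a zero field", {
  spec <- small_spec(seed = 1, noise_sd = 0, taper = 0)
  tube <- make_tube(spec)
  expect_true(all(tube$field$vectors == 0))

  # wall mask equals the analytic annulus voxel set
  d <- spec$shape
  xs <- (seq_len(d[1]) - 1) * spec$spacing[1]
  ys <- (seq_len(d[2]) - 1) * spec$spacing[2]
  cx <- mean(range(xs)); cy <- mean(range(ys))
  r <- sqrt(outer((xs - cx)^2, (ys - cy)^2, "+"))
  wall2d <- r >= spec$inner_radius & r < spec$outer_radius
  for (k in c(1, 6, 12))
    expect_identical(tube$mask$labels[, , k] == 1L, wall2d)
})

test_that("planted inward vectors have exact norm and point at the centroid", {
  a <- 2.5
  tube <- make_tube(small_spec(deformation = "inward_radial", amplitude = a,
                               taper = 0, seed = 2))
  rv <- stodeo:::field_roi_vectors(tube$field)
  norms <- sqrt(rowSums(rv$vectors^2))
  expect_true(all(abs(norms - a) < 1e-9))
  # angle to the in-plane lumen centroid < 20 degrees (exactly ~0 here)
  ang <- orientation_field(tube$field,
                           stodeo:::section_lumen_centroids(tube$canonical$mask,
                                                            rv$idx))
  expect_true(all(ang < 20))
})

test_that("phantom generation honors the seed contract", {
  s1 <- make_tube(small_spec(seed = 10, noise_sd = 0.05))
  s2 <- make_tube(small_spec(seed = 10, noise_sd = 0.05))
  s3 <- make_tube(small_spec(seed = 11, noise_sd = 0.05))
  expect_identical(s1$volume$voxels, s2$volume$voxels)
  expect_identical(s1$mask$labels, s3$mask$labels)      # geometry seed-free
  expect_false(identical(s1$volume$voxels, s3$volume$voxels))
})

test_that("cohort composition mirrors the requested class mix", {
  co <- make_cohort(88, class_mix = 0.36, seed = 1)
  expect_equal(sum(co$manifest$label == "responder"), 32)
  expect_equal(nrow(co$manifest), 88)
  expect_false(anyDuplicated(co$manifest$id) > 0)

  co2 <- make_cohort(2, class_mix = 0.5, seed = 1)
  expect_setequal(co2$manifest$label, c("responder", "non-responder"))
  expect_error(make_cohort(10, class_mix = 1.2), "class_mix")
  expect_error(make_cohort(1), ">= 2")
})

test_that("cell-count generator plants recoverable correlations", {
  set.seed(3)
  feats <- data.frame(f1 = rnorm(60), f2 = rnorm(60), f3 = rnorm(60))
  # null coupling: correlations near zero
  null_counts <- make_cell_counts(feats, matrix(0, 4, 3), seed = 5)
  rho0 <- abs(cor(null_counts$CD8, feats$f1, method = "spearman"))
  expect_lt(rho0, 0.35)
  # strong coupling on one (cell, feature) pair is recoverable
  cpl <- matrix(0, 4, 3); cpl[1, 1] <- 0.9
  counts <- make_cell_counts(feats, cpl, seed = 5)
  expect_gt(cor(counts$CD8, feats$f1, method = "spearman"), 0.5)
  # deterministic per seed
  expect_identical(counts, make_cell_counts(feats, cpl, seed = 5))
})
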