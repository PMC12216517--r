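make_field <- function(vectors_by_voxel, dims = NULL) {
  # vectors_by_voxel: n x 3; laid out along the first array axis
  n <- nrow(vectors_by_voxel)
  if (is.null(dims)) dims <- c(n, 1L, 1L)
  v <- array(0, c(dims, 3))
  idx <- which(array(TRUE, dims), arr.ind = TRUE)[seq_len(n), , drop = FALSE]
  for (d in 1:3) v[cbind(idx, d)] <- vectors_by_voxel[, d]
  roi <- array(FALSE, dims)
  roi[idx] <- TRUE
  deformation_field(v, roi = roi)
}

test_that("magnitude field equals the per-voxel Euclidean norm", {
  f <- make_field(rbind(c(3, 4, 0), c(0, 0, 0), c(1, 2, 2)))
  expect_equal(magnitude_field(f)$values, c(5, 0, 3))

  set.seed(1)
  vv <- matrix(rnorm(3000), ncol = 3)
  mags <- magnitude_field(make_field(vv))$values
  # independent element-wise recomputation
  oracle <- apply(vv, 1, function(r) sqrt(r[1]^2 + r[2]^2 + r[3]^2))
  expect_equal(mags, oracle, tolerance = 1e-12)
})

test_that("magnitude statistics follow the declared estimator conventions", {
  expect_equal(magnitude_statistics(rep(2, 50)),
               c(median_mag = 2, std_mag = 0, skew_mag = 0, kurt_mag = 0))

  x <- c(1, 2, 3, 4, 5)
  st <- magnitude_statistics(x)
  m <- mean(x); m2 <- mean((x - m)^2)
  expect_equal(unname(st["median_mag"]), 3)
  expect_equal(unname(st["std_mag"]), sd(x))
  expect_equal(unname(st["skew_mag"]), mean((x - m)^3) / m2^1.5)
  expect_equal(unname(st["kurt_mag"]), mean((x - m)^4) / m2^2 - 3)

  # symmetric bimodal sample: skewness vanishes
  sym <- c(rep(1, 40), rep(9, 40))
  expect_lt(abs(magnitude_statistics(sym)["skew_mag"]), 1e-10)
  expect_error(magnitude_statistics(numeric(0)), "empty")
})

test_that("deformation angles reproduce the analytic arccos cases", {
  cen <- c(10, 0, 0)
  pts_field <- function(v) {
    f <- make_field(matrix(v, 1))
    orientation_field(f, cen)   # voxel at physical (0,0,0)
  }
  expect_equal(as.numeric(pts_field(c(2, 0, 0))), 0, tolerance = 1e-9)
  expect_equal(as.numeric(pts_field(c(-2, 0, 0))), 180, tolerance = 1e-9)
  expect_equal(as.numeric(pts_field(c(0, 3, 0))), 90, tolerance = 1e-9)
  # zero vectors are skipped and counted
  f0 <- make_field(rbind(c(0, 0, 0), c(1, 0, 0)))
  a <- orientation_field(f0, cen)
  expect_equal(length(a), 1L)
  expect_equal(attr(a, "n_skipped"), 1L)
})

test_that("orientation histogram uses the published five-bin quantization", {
  expect_equal(unname(orientation_histogram(c(10, 15))), c(1, 0, 0, 0, 0))
  expect_equal(unname(orientation_histogram(c(170, 175, 180))),
               c(0, 0, 0, 0, 1))
  expect_equal(unname(orientation_histogram(c(20))), c(0, 1, 0, 0, 0))
  expect_warning(h0 <- orientation_histogram(numeric(0)), "no valid")
  expect_equal(unname(h0), rep(0, 5))

  # uniform angles: masses near the bin widths (20,60,20,60,20)/180
  set.seed(2)
  ang <- runif(1e4, 0, 180)
  h <- orientation_histogram(ang)
  expected <- c(20, 60, 20, 60, 20) / 180
  sds <- sqrt(expected * (1 - expected) / 1e4)
  expect_true(all(abs(h - expected) < 3 * sds))
  expect_equal(sum(h), 1)
})

test_that("negating every vector exchanges bin k with bin 6-k exactly", {
  set.seed(3)
  n <- 4000
  vv <- matrix(rnorm(3 * n), ncol = 3)
  cen <- c(50, 50, 0)
  f <- make_field(vv, dims = c(n, 1L, 1L))
  fneg <- make_field(-vv, dims = c(n, 1L, 1L))
  h <- orientation_histogram(orientation_field(f, cen))
  hneg <- orientation_histogram(orientation_field(fneg, cen))
  expect_identical(unname(h), unname(rev(hneg)))
  # include exact boundary angles: 20/80/100/160 degrees map consistently
  ang <- c(0, 20, 80, 100, 160, 180)
  h2 <- orientation_histogram(ang)
  h2n <- orientation_histogram(180 - ang)
  expect_identical(unname(h2), unname(rev(h2n)))
})

test_that("angles are invariant to uniform positive scaling of the field", {
  set.seed(4)
  vv <- matrix(rnorm(300), ncol = 3)
  f1 <- make_field(vv)
  f2 <- make_field(vv * 7.3)
  cen <- c(30, -10, 5)
  expect_equal(as.numeric(orientation_field(f1, cen)),
               as.numeric(orientation_field(f2, cen)), tolerance = 1e-9)
  # magnitudes are preserved under a global rotation of field and geometry
  th <- 0.7
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3,
              byrow = TRUE)
  expect_equal(magnitude_field(make_field(vv %*% t(R)))$values,
               magnitude_field(f1)$values, tolerance = 1e-12)
})

test_that("MRF clustering isolates a planted high-deformation region", {
  # planted two-level magnitude field on a 2-D sheet with the published
  # parameters (6 classes, 8 iterations, potential 0.5)
  set.seed(5)
  dims <- c(40, 40, 1)
  truth <- array(FALSE, dims)
  truth[1:20, , 1] <- TRUE
  mags <- array(0.5, dims) + array(rnorm(prod(dims), 0, 0.1), dims)
  mags[truth] <- 5 + rnorm(sum(truth), 0, 0.1)
  roi <- array(TRUE, dims)
  v <- array(0, c(dims, 3))
  v[, , , 1] <- mags
  f <- deformation_field(v, roi = roi)
  mag <- magnitude_field(f)
  high <- mrf_isolate_high_deformation(mag, n_classes = 6, n_iters = 8,
                                       beta = 0.5, seed = 1)
  est <- array(FALSE, dims)
  est[mag$idx[high, , drop = FALSE]] <- TRUE
  dice <- 2 * sum(est & truth) / (sum(est) + sum(truth))
  expect_gte(dice, 0.95)
})

test_that("MRF degenerate and regularization behaviours", {
  # constant field: single effective class covering the whole ROI
  dims <- c(10, 10, 1)
  v <- array(0, c(dims, 3)); v[, , , 1] <- 2
  f <- deformation_field(v, roi = array(TRUE, dims))
  out <- mrf_isolate_high_deformation(magnitude_field(f))
  expect_true(all(out))

  # salt-and-pepper outliers: beta = 0.5 yields fewer isolated labels than
  # beta = 0 (spatial smoothing of the label field)
  set.seed(6)
  dims <- c(30, 30, 1)
  base <- array(1 + 0.05 * rnorm(900), dims)
  spots <- sample(900, 25)
  base[spots] <- 6
  v <- array(0, c(dims, 3)); v[, , , 1] <- base
  f <- deformation_field(v, roi = array(TRUE, dims))
  mag <- magnitude_field(f)
  isolated_count <- function(beta) {
    lab <- attr(mrf_isolate_high_deformation(mag, beta = beta, seed = 2),
                "labels")
    grid <- array(lab, dims[1:2])
    iso <- 0
    for (i in 2:(dims[1] - 1)) for (j in 2:(dims[2] - 1)) {
      nb <- c(grid[i - 1, j], grid[i + 1, j], grid[i, j - 1], grid[i, j + 1])
      if (all(nb != grid[i, j])) iso <- iso + 1
    }
    iso
  }
  expect_lt(isolated_count(0.5), isolated_count(0))
})

test_that("compute_stodeo recovers planted phantom deformations end to end", {
  a <- 3
  inw <- make_tube(small_spec(deformation = "inward_radial", amplitude = a,
                              seed = 7))
  d_in <- compute_stodeo(inw$field, inw$canonical$mask, "single_section")
  expect_lt(abs(d_in$f_m["median_mag"] - a) / a, 0.2)
  expect_gte(d_in$f_o["fo_bin1"], 0.8)
  expect_equal(sum(d_in$f_o), 1)

  outw <- make_tube(small_spec(deformation = "outward_radial", amplitude = a,
                               seed = 8))
  d_out <- compute_stodeo(outw$field, outw$canonical$mask, "single_section")
  expect_gte(d_out$f_o["fo_bin5"], 0.8)

  # zero field: zero statistics and an all-zero histogram with a warning
  none <- make_tube(small_spec(seed = 9))
  expect_warning(d0 <- compute_stodeo(none$field, none$canonical$mask,
                                      "single_section"), "zero deformation")
  expect_equal(unname(d0$f_m), c(0, 0, 0, 0))
  expect_equal(unname(d0$f_o), rep(0, 5))
})

test_that("inward and outward cohorts separate perfectly by bin1 - bin5", {
  sep <- vapply(1:6, function(i) {
    kind <- if (i <= 3) "inward_radial" else "outward_radial"
    tube <- make_tube(small_spec(deformation = kind, amplitude = 2 + i %% 3,
                                 seed = 20 + i))
    d <- compute_stodeo(tube$field, tube$canonical$mask, "single_section")
    unname(d$f_o["fo_bin1"] - d$f_o["fo_bin5"])
  }, numeric(1))
  expect_true(all(sep[1:3] > 0))
  expect_true(all(sep[4:6] < 0))
})
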