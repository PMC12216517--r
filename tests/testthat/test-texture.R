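# direct correlation oracle for the convolution engine
filter2_oracle <- function(img, kern) {
  kr <- (dim(kern)[1] - 1) / 2
  kc <- (dim(kern)[2] - 1) / 2
  n1 <- nrow(img); n2 <- ncol(img)
  ridx <- function(i, n) {
    i <- ((i - 1) %% (2 * n)) + 1
    ifelse(i > n, 2 * n + 1 - i, i)
  }
  out <- matrix(0, n1, n2)
  for (i in 1:n1) for (j in 1:n2) {
    acc <- 0
    for (a in -kr:kr) for (b in -kc:kc)
      acc <- acc + kern[a + kr + 1, b + kc + 1] *
        img[ridx(i + a, n1), ridx(j + b, n2)]
    out[i, j] <- acc
  }
  out
}

test_that("the convolution engine matches a direct correlation oracle", {
  set.seed(1)
  img <- matrix(rnorm(20 * 16), 20, 16)
  kern <- matrix(rnorm(9), 3, 3)
  expect_equal(stodeo:::conv2_reflect(img, kern), filter2_oracle(img, kern),
               tolerance = 1e-10)
})

test_that("Gabor responses behave as matched oriented filters", {
  # constant image: zero-mean kernel gives (near) zero response
  const <- matrix(5, 48, 48)
  r0 <- gabor_response(const, 0, 4)
  expect_lt(max(abs(r0)), 1e-8)

  # impulse image: response reproduces the kernel around the impulse
  imp <- matrix(0, 41, 41)
  imp[21, 21] <- 1
  r1 <- gabor_response(imp, 45, 4)
  k <- attr(r1, "kernel")
  half <- (nrow(k) - 1) / 2
  sub <- r1[(21 - half):(21 + half), (21 - half):(21 + half)]
  expect_equal(sub, unname(k), tolerance = 1e-8)

  # sinusoidal grating: the matched orientation/wavelength wins in the bank
  xs <- seq_len(48)
  grating <- outer(xs, xs, function(x, y) sin(2 * pi * x / 8))  # along x, w=8
  bank <- expand.grid(ori = c(0, 45, 90, 135), w = c(4, 8, 16))
  resp <- apply(bank, 1, function(b)
    mean(abs(suppressWarnings(gabor_response(grating, b[1], b[2])))))
  best <- bank[which.max(resp), ]
  expect_equal(unname(unlist(best)), c(0, 8))
})

test_that("Sobel gradients match the analytic ramp and edge responses", {
  # constant image: zero everywhere
  expect_lt(max(abs(sobel_gradient(matrix(2, 20, 20), "X"))), 1e-10)

  # linear ramp along x with slope s: interior X response is 8 * s
  s <- 0.7
  ramp <- matrix(rep((1:24) * s, times = 20), 24, 20)
  rx <- sobel_gradient(ramp, "X")
  expect_equal(max(abs(rx[5:20, 5:15] - 8 * s)), 0, tolerance = 1e-10)
  # direct convolution oracle on the same ramp
  expect_equal(rx, filter2_oracle(ramp, stodeo:::sobel_kernels$X),
               tolerance = 1e-10)

  # vertical step edge: |response| maximal on the edge rows
  step <- matrix(0, 20, 20)
  step[11:20, ] <- 1
  ry <- abs(sobel_gradient(step, "X"))
  expect_true(all(ry[10, 5:15] >= apply(ry[c(2:8, 13:19), 5:15], 2, max)))

  # diagonal variants are distinct filters
  expect_false(identical(sobel_gradient(step, "XY"), sobel_gradient(step, "YX")))
})

test_that("CoLlAGe maps follow degenerate conventions and a brute-force oracle", {
  # constant image: all neutral, idm = 1, info1 = 0
  const <- matrix(1, 15, 15)
  roi <- matrix(FALSE, 15, 15); roi[6:10, 6:10] <- TRUE
  maps <- collage_features(const, roi)
  expect_equal(attr(maps, "n_neutral"), sum(roi))
  expect_true(all(maps$idm[roi] == 1))
  expect_true(all(maps$info1[roi] == 0))

  # single-orientation ramp: one occupied level, diagonal co-occurrence,
  # idm exactly 1
  ramp <- matrix(rep(1:20, times = 20), 20, 20)
  roi2 <- matrix(FALSE, 20, 20); roi2[8:12, 8:12] <- TRUE
  maps2 <- collage_features(ramp, roi2)
  expect_true(all(abs(maps2$idm[roi2] - 1) < 1e-12))

  # random texture: info1/idm equal an independent brute-force co-occurrence
  # computation on the same quantized window
  set.seed(3)
  img <- matrix(rnorm(25 * 25), 25, 25)
  roi3 <- matrix(FALSE, 25, 25); roi3[13, 13] <- TRUE
  maps3 <- collage_features(img, roi3, window_size = 5, n_levels = 16)
  # oracle: recompute quantized orientations + GLCM by hand
  gx <- filter2_oracle(img, stodeo:::sobel_kernels$X)
  gy <- filter2_oracle(img, stodeo:::sobel_kernels$Y)
  lev <- matrix(0, 25, 25)
  for (i in 1:25) for (j in 1:25) {
    i0 <- max(1, i - 2):min(25, i + 2)
    j0 <- max(1, j - 2):min(25, j + 2)
    G <- cbind(as.vector(gx[i0, j0]), as.vector(gy[i0, j0]))
    S <- crossprod(G)
    th <- (0.5 * atan2(2 * S[1, 2], S[1, 1] - S[2, 2])) %% pi
    lev[i, j] <- min(15, floor(th / pi * 16)) + 1
  }
  w <- lev[11:15, 11:15]
  pairs <- rbind(
    cbind(as.vector(w[-5, ]), as.vector(w[-1, ])),
    cbind(as.vector(w[, -5]), as.vector(w[, -1])))
  pairs <- rbind(pairs, pairs[, 2:1])
  p <- table(paste(pairs[, 1], pairs[, 2])) / nrow(pairs)
  ij <- do.call(rbind, strsplit(names(p), " "))
  pi_ <- as.numeric(ij[, 1]); pj_ <- as.numeric(ij[, 2]); pv <- as.numeric(p)
  idm_oracle <- sum(pv / (1 + (pi_ - pj_)^2))
  expect_equal(maps3$idm[13, 13], idm_oracle, tolerance = 1e-10)
  lvls <- sort(unique(c(pi_, pj_)))
  px <- vapply(lvls, function(l) sum(pv[pi_ == l]), numeric(1))
  hx <- -sum(px[px > 0] * log(px[px > 0]))
  hxy <- -sum(pv * log(pv))
  hxy1 <- -sum(pv * log(px[match(pi_, lvls)] * px[match(pj_, lvls)]))
  info1_oracle <- (hxy - hxy1) / hx
  expect_equal(maps3$info1[13, 13], info1_oracle, tolerance = 1e-10)
  # documented ranges
  expect_true(maps3$idm[13, 13] > 0 && maps3$idm[13, 13] <= 1)
  expect_true(maps3$info1[13, 13] >= -1 && maps3$info1[13, 13] <= 0)
})

test_that("first-order aggregation matches hand computation and pooling", {
  m <- matrix(c(0, 0, 0, 10), 2, 2)
  roi <- matrix(TRUE, 2, 2)
  ag <- aggregate_first_order(m, roi)
  x <- c(0, 0, 0, 10)
  mu <- mean(x); m2 <- mean((x - mu)^2)
  expect_equal(unname(ag["Median"]), 0)
  expect_equal(unname(ag["Variance"]), var(x))
  expect_equal(unname(ag["Std"]), sd(x))
  expect_equal(unname(ag["Skewness"]), mean((x - mu)^3) / m2^1.5)
  expect_equal(unname(ag["Kurtosis"]), mean((x - mu)^4) / m2^2 - 3)

  cst <- aggregate_first_order(matrix(4, 3, 3), matrix(TRUE, 3, 3))
  expect_equal(unname(cst[c("Variance", "Skewness")]), c(0, 0))

  # pooling identity for mean/variance over a disjoint partition
  set.seed(4)
  vals <- rnorm(60)
  a <- vals[1:25]; b <- vals[26:60]
  na <- length(a); nb <- length(b); n <- na + nb
  pooled_mean <- (na * mean(a) + nb * mean(b)) / n
  pooled_var <- ((na - 1) * var(a) + (nb - 1) * var(b) +
                 na * (mean(a) - pooled_mean)^2 +
                 nb * (mean(b) - pooled_mean)^2) / (n - 1)
  whole <- aggregate_first_order(matrix(vals), matrix(TRUE, 60, 1))
  expect_equal(unname(whole["Variance"]), pooled_var)
  expect_equal(unname(whole["Variance"]), var(vals))
})

test_that("texture extraction is shift-invariant, keyed stably, reproducible", {
  tube <- make_tube(small_spec(seed = 12, heterogeneity = 0.3))
  f1 <- extract_texture_features(tube$volume, tube$mask, "single_section")
  # gradient/Gabor families invariant to adding an intensity constant
  shifted <- image_volume(tube$volume$voxels + 11, tube$volume$spacing,
                          tube$volume$origin)
  f2 <- extract_texture_features(shifted, tube$mask, "single_section")
  expect_equal(f1, f2, tolerance = 1e-6)
  # bit reproducibility and stable keys
  f3 <- extract_texture_features(tube$volume, tube$mask, "single_section")
  expect_identical(f1, f3)
  expect_true(all(c("Skewness—Gabor XY w=4", "Variance—CoLlAGe idm ws=5",
                    "Skewness—Gradient Sobel YX") %in% names(f1)))
  expect_gte(attr(f1, "bank_size"), 100)
})
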