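two_blobs <- function(n = 60, d = 10, delta = 10, seed = 1) {
  # each class shares a strong mean *profile* (opposite between classes):
  # Pearson profile distance sees neither a constant offset nor pure noise,
  # so clouds must be profile-coherent to cluster exactly — as embeddings of
  # genuinely distinct classes are
  set.seed(seed)
  half <- n %/% 2
  prof <- delta * rep_len(c(1, -1), d)
  x <- rbind(sweep(matrix(rnorm(half * d), half), 2, prof, "+"),
             sweep(matrix(rnorm((n - half) * d), n - half), 2, -prof, "+"))
  list(x = x, truth = rep(c("responder", "non-responder"), c(half, n - half)))
}

test_that("t-SNE co-locates duplicates and separates planted blobs", {
  b <- two_blobs(n = 60, delta = 10)
  x <- b$x
  x[2, ] <- x[1, ]                       # exact duplicate pair
  expect_warning(emb <- tsne_project(x, dims = 3, seed = 5), "perplexity")
  d12 <- sqrt(sum((emb[1, ] - emb[2, ])^2))
  dall <- median(as.matrix(dist(emb))[upper.tri(diag(60))])
  expect_lt(d12, 0.1 * dall)

  # 2-means on the embedding recovers the blob labels
  km <- kmeans(emb, 2, nstart = 5)
  agree <- max(mean((km$cluster == 1) == (b$truth == "responder")),
               mean((km$cluster == 2) == (b$truth == "responder")))
  expect_gte(agree, 0.95)

  # deterministic given the seed
  expect_identical(suppressWarnings(tsne_project(x, seed = 5)),
                   suppressWarnings(tsne_project(x, seed = 5)))
})

test_that("consensus clustering produces exact block structure on separated clouds", {
  b <- two_blobs(n = 24, d = 5, delta = 12, seed = 2)
  cc <- consensus_cluster(b$x, k = 2, iters = 300, seed = 3)
  expect_true(isSymmetric(cc$consensus))
  expect_true(all(diag(cc$consensus) == 1))
  expect_true(all(cc$consensus >= 0 & cc$consensus <= 1))
  same <- outer(b$truth, b$truth, "==")
  off <- !diag(TRUE, 24)
  expect_true(all(cc$consensus[same & off] == 1))
  expect_true(all(cc$consensus[!same] == 0))
  expect_equal(cluster_overlap_accuracy(cc$assignment, b$truth), 1.0)
})

test_that("a single tight cloud yields an unstable forced split", {
  set.seed(4)
  x <- matrix(rnorm(30 * 4), 30)
  cc <- consensus_cluster(x, k = 2, iters = 300, seed = 5)
  within <- vapply(unique(cc$assignment), function(k) {
    rows <- which(cc$assignment == k)
    if (length(rows) < 2) return(NA_real_)
    m <- cc$consensus[rows, rows]
    mean(m[upper.tri(m)])
  }, numeric(1))
  expect_lt(mean(within, na.rm = TRUE), 0.9)
})

test_that("pair co-sampling counts follow the resampling arithmetic", {
  set.seed(6)
  x <- matrix(rnorm(20 * 3), 20)
  iters <- 500
  cc <- consensus_cluster(x, k = 2, iters = iters, resample = 0.8, seed = 7)
  co <- cc$cosample[upper.tri(cc$cosample)]
  # floor(0.8 * 20) = 16 of 20 sampled: pair probability (16/20) * (15/19)
  p <- (16 / 20) * (15 / 19)
  expect_true(all(abs(co - iters * p) < 3 * sqrt(iters * p * (1 - p)) + 1))
})

test_that("overlap accuracy is label- and cluster-permutation invariant", {
  y <- rep(c("responder", "non-responder"), c(10, 14))
  assign1 <- c(rep(1, 10), rep(2, 14))
  expect_equal(cluster_overlap_accuracy(assign1, y), 1.0)
  expect_equal(cluster_overlap_accuracy(3 - assign1, y), 1.0)

  # random assignments over many repeats agree with an exhaustive-matching
  # recomputation
  set.seed(8)
  vals <- replicate(200, {
    a <- sample(1:2, 24, replace = TRUE)
    if (length(unique(a)) < 2) return(NA_real_)
    acc <- cluster_overlap_accuracy(a, y[1:24])
    yb <- y[1:24] == "responder"
    frac <- vapply(1:2, function(k) mean(yb[a == k]), numeric(1))
    oracle <- sum(yb & a == which.max(frac)) / sum(yb)
    expect_equal(acc, oracle)
    acc
  })
  expect_gt(mean(vals, na.rm = TRUE), 0.4)
})

test_that("Spearman maps flag monotone pairs and respect rank invariance", {
  set.seed(9)
  n <- 19
  f <- data.frame(fa = rnorm(n), fb = rnorm(n))
  cells <- data.frame(CD8 = sort(runif(n))[rank(f$fa)],      # monotone in fa
                      CD4 = -f$fb^3 + 0,                      # monotone dec
                      Treg = rnorm(n), macrophage = rep(1, n))
  cells$CD4 <- -(f$fb + 10)^3
  m <- spearman_fdr_map(f, cells)
  expect_equal(m$rho[m$cell == "CD8" & m$feature == "fa"], 1)
  expect_equal(m$rho[m$cell == "CD4" & m$feature == "fb"], -1)
  expect_true(all(is.na(m$rho[m$cell == "macrophage"])))   # constant column
  expect_true(all(abs(m$rho) <= 1, na.rm = TRUE))

  # invariance under strictly monotone transforms of either variable
  f2 <- f
  f2$fa <- exp(f$fa)
  m2 <- spearman_fdr_map(f2, cells)
  expect_equal(m$rho[m$feature == "fa"], m2$rho[m2$feature == "fa"])
  expect_error(spearman_fdr_map(f[1:3, ], cells[1:3, ]), ">= 5")
})

test_that("null cell maps keep the q-value flag rate at the nominal level", {
  # all-null synthetic maps: flags must stay consistent with an independent
  # Benjamini-Hochberg step-up oracle at the same threshold
  set.seed(10)
  reps <- 120
  flag_frac <- bh_frac <- numeric(reps)
  for (r in seq_len(reps)) {
    f <- as.data.frame(matrix(rnorm(19 * 6), 19))
    cells <- as.data.frame(matrix(rnorm(19 * 5), 19))
    names(cells) <- c("CD8", "CD4", "Treg", "macrophage", "other")
    m <- spearman_fdr_map(f, cells, fdr_threshold = 0.3)
    flag_frac[r] <- mean(m$flag)
    bh <- p.adjust(m$p, "BH") <= 0.3
    bh_frac[r] <- mean(bh)
  }
  # Storey q-values are less conservative than BH but must stay of the same
  # order on null data; both should flag (far) less than the 30% level
  expect_lt(mean(flag_frac), 0.15)
  expect_lt(abs(mean(flag_frac) - mean(bh_frac)), 0.10)
})

test_that("planted radiomic-cell couplings are recovered through the map", {
  set.seed(11)
  hits <- vapply(1:25, function(r) {
    f <- data.frame(f1 = rnorm(19), f2 = rnorm(19))
    cpl <- matrix(0, 4, 2)
    cpl[1, 1] <- 0.85
    cells <- make_cell_counts(f, cpl, seed = 100 + r)
    m <- spearman_fdr_map(f, cells)
    m$flag[m$cell == "CD8" & m$feature == "f1"]
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})
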