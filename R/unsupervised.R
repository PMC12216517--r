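# Unsupervised evaluation: t-SNE projection, resampled hierarchical
# consensus clustering with Pearson distance, cluster/label overlap
# accuracy, and Spearman correlation cell maps with Storey positive-FDR
# q-values.

#' t-SNE projection of a feature table
#'
#' Projects standardized features into `dims` dimensions with t-SNE
#' (Euclidean metric, random initialization, `iters` iterations). The
#' published "30 nearest neighbors" setting is interpreted as perplexity 30;
#' when the cohort is too small for that perplexity it is reduced to
#' `floor((n - 1) / 3)` with a warning.
#'
#' @param x numeric matrix/data.frame (patients x features).
#' @param dims embedding dimensionality (default 3).
#' @param neighbors perplexity (default 30).
#' @param iters gradient-descent iterations (default 1000).
#' @param seed integer seed; the embedding is deterministic given it.
#' @return n x dims embedding matrix.
#' @export
tsne_project <- function(x, dims = 3, neighbors = 30, iters = 1000, seed = 1L) {
  x <- as.matrix(x)
  if (nrow(x) < dims + 2) stop("too few rows for a ", dims, "-D embedding")
  z <- scale(x)
  z[!is.finite(z)] <- 0
  z <- z[, apply(z, 2, function(v) any(v != 0)), drop = FALSE]
  perp <- neighbors
  if (nrow(z) - 1 < 3 * perp) {
    perp <- max(2, floor((nrow(z) - 1) / 3))
    warning("perplexity reduced to ", perp, " for n = ", nrow(z))
  }
  set.seed(seed)
  fit <- Rtsne::Rtsne(z, dims = dims, perplexity = perp, max_iter = iters,
                      theta = if (nrow(z) <= 500) 0 else 0.5,
                      check_duplicates = FALSE, pca = nrow(z) > 50,
                      verbose = FALSE)
  fit$Y
}

# Pearson-correlation distance between rows; constant rows get a tiny
# deterministic jitter so the correlation is defined
pearson_distance <- function(m, eps = 1e-8) {
  const <- apply(m, 1, function(r) stats::var(r) < 1e-24)
  if (any(const)) {
    jit <- outer(seq_len(nrow(m)), seq_len(ncol(m)),
                 function(i, j) sin(i * 7 + j * 13))
    m[const, ] <- m[const, , drop = FALSE] + eps * jit[const, , drop = FALSE]
  }
  as.dist(1 - cor(t(m)))
}

#' Resampled hierarchical consensus clustering
#'
#' Repeatedly subsamples `resample` of the patients, clusters each subsample
#' by average-linkage hierarchical clustering with Pearson-correlation
#' distance cut at `k`, and records how often each pair of patients lands in
#' the same cluster among the iterations where both were sampled. The final
#' assignment cuts an average-linkage tree of `1 - consensus` at `k`.
#'
#' @param x numeric matrix (patients x dims; typically the t-SNE embedding).
#' @param k cluster count (default 2).
#' @param iters resampling iterations (default 1000).
#' @param resample subsample fraction (default 0.8).
#' @param seed integer seed.
#' @return object of class `consensus_result`: `consensus` (n x n, symmetric,
#'   unit diagonal), `assignment`, `cosample` (pair sampling counts),
#'   `iters`.
#' @export
consensus_cluster <- function(x, k = 2, iters = 1000, resample = 0.8,
                              seed = 1L) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 4) stop("consensus clustering needs >= 4 points")
  set.seed(seed)
  co <- matrix(0, n, n)
  together <- matrix(0, n, n)
  m <- max(2, floor(resample * n))
  for (it in seq_len(iters)) {
    rows <- sample.int(n, m)
    cl <- cutree(hclust(pearson_distance(x[rows, , drop = FALSE]),
                        method = "average"), k = k)
    co[rows, rows] <- co[rows, rows] + 1
    for (cc in seq_len(k)) {
      rc <- rows[cl == cc]
      together[rc, rc] <- together[rc, rc] + 1
    }
  }
  consensus <- ifelse(co > 0, together / pmax(co, 1), 0)
  diag(consensus) <- 1
  assignment <- cutree(hclust(as.dist(1 - consensus), method = "average"),
                       k = k)
  structure(list(consensus = consensus, assignment = assignment,
                 cosample = co, iters = iters, resample = resample),
            class = "consensus_result")
}

#' @export
print.consensus_result <- function(x, ...) {
  cat(sprintf("<consensus_result> %d patients, k = %d, %d iterations\n",
              nrow(x$consensus), length(unique(x$assignment)), x$iters))
  invisible(x)
}

#' Overlap accuracy of a 2-cluster assignment against response labels
#'
#' Matches clusters to labels by responder majority and returns the fraction
#' of responders captured by the responder-majority cluster. Invariant to
#' permuting the cluster indices.
#'
#' @param assignment integer cluster labels (k = 2).
#' @param labels response labels (`"responder"` positive) or logical.
#' @return fraction in `[0, 1]`.
#' @export
cluster_overlap_accuracy <- function(assignment, labels) {
  y <- as_binary_label(labels)
  if (!any(y) || all(y)) stop("overlap accuracy undefined: single-class labels")
  ks <- unique(assignment)
  if (length(ks) != 2) stop("expected a 2-cluster assignment")
  frac <- vapply(ks, function(kk) mean(y[assignment == kk]), numeric(1))
  responder_cluster <- ks[which.max(frac)]
  sum(y & assignment == responder_cluster) / sum(y)
}

# Storey positive-FDR q-values: pi0 from a lambda grid with a cubic-spline
# smoother (as in the reference implementation), then step-up q-values
storey_qvalue <- function(p, lambda = seq(0.05, 0.95, 0.05)) {
  m <- length(p)
  if (m == 0) return(numeric(0))
  pi0l <- vapply(lambda, function(l) mean(p > l) / (1 - l), numeric(1))
  pi0 <- if (m < 100) {
    min(1, 2 * mean(p > 0.5))           # conservative small-m estimate
  } else {
    sp <- smooth.spline(lambda, pi0l, df = 3)
    max(min(predict(sp, max(lambda))$y, 1), 0)
  }
  if (pi0 <= 0) pi0 <- 1e-8
  ord <- order(p, decreasing = TRUE)
  q <- numeric(m)
  prev <- 1
  for (i in ord) {
    rank_i <- sum(p <= p[i])
    prev <- min(prev, pi0 * p[i] * m / rank_i)
    q[i] <- prev
  }
  q
}

#' Spearman correlation cell map with positive-FDR flags
#'
#' Spearman's rank correlation between every (cell-type, feature) pair, with
#' Storey positive-FDR q-values computed across all cells of the map; cells
#' with q-values above `fdr_threshold` are considered non-relevant (only
#' `q <= fdr_threshold` cells are flagged). Constant columns yield undefined
#' correlations and are reported as NA.
#'
#' @param features data.frame/matrix of radiomic features (rows = patients).
#' @param cell_counts data.frame/matrix of normalized cell counts (same
#'   rows).
#' @param fdr_threshold q-value flag threshold (default 0.3).
#' @return data.frame with columns `cell`, `feature`, `rho`, `p`, `q`,
#'   `flag`.
#' @export
spearman_fdr_map <- function(features, cell_counts, fdr_threshold = 0.3) {
  features <- as.data.frame(features)
  cell_counts <- as.data.frame(cell_counts)
  if (nrow(features) != nrow(cell_counts))
    stop("features and cell_counts must have paired rows")
  if (nrow(features) < 5) stop("need >= 5 paired observations per cell")
  grid <- expand.grid(cell = names(cell_counts), feature = names(features),
                      stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    a <- cell_counts[[grid$cell[i]]]
    b <- features[[grid$feature[i]]]
    if (length(unique(a)) == 1 || length(unique(b)) == 1)
      return(c(rho = NA_real_, p = NA_real_))
    ct <- suppressWarnings(stats::cor.test(a, b, method = "spearman"))
    c(rho = unname(ct$estimate), p = ct$p.value)
  })
  out <- cbind(grid, do.call(rbind, res))
  ok <- !is.na(out$p)
  out$q <- NA_real_
  out$q[ok] <- storey_qvalue(out$p[ok])
  out$flag <- !is.na(out$q) & out$q <= fdr_threshold
  out
}
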