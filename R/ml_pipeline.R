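# Supervised evaluation machinery: mRMR feature selection, LDA/QDA/RF
# classifiers, repeated stratified cross-validation with bootstrapped AUCs,
# hold-out evaluation, clinical baselines, and robustness statistics.
# The positive class throughout is "responder" (pathologic downstaging).

METADATA_COLUMNS <- c("id", "label", "institution", "scanner", "sex",
                      "field_strength", "annotation", "cohort", "ctnm")

#' Feature columns of a feature table
#'
#' @param table a feature data.frame (patients x features + metadata).
#' @return character vector of feature column names.
#' @export
feature_columns <- function(table) {
  setdiff(names(table), METADATA_COLUMNS)
}

check_feature_table <- function(table) {
  if (!"label" %in% names(table)) stop("feature table must have a label column")
  if ("id" %in% names(table) && anyDuplicated(table$id))
    stop("duplicated patient ids in feature table")
  invisible(table)
}

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) AUC of scores against binary labels.
#'
#' @param scores numeric scores, larger = more positive.
#' @param labels logical or two-level vector; `TRUE`/`"responder"` positive.
#' @return AUC in `[0, 1]`.
#' @export
auc_score <- function(scores, labels) {
  y <- as_binary_label(labels)
  n1 <- sum(y)
  n0 <- sum(!y)
  if (n1 == 0 || n0 == 0) stop("AUC undefined: validation set has one class")
  r <- rank(scores)
  (sum(r[y]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

as_binary_label <- function(labels) {
  if (is.logical(labels)) return(labels)
  labels <- as.character(labels)
  if ("responder" %in% labels) labels == "responder"
  else labels == sort(unique(labels))[min(2, length(unique(labels)))]
}

# equal-frequency discretization into `bins` levels (tertiles by default)
discretize_ef <- function(x, bins = 3) {
  qs <- unique(quantile(x, probs = seq(0, 1, length.out = bins + 1),
                        na.rm = TRUE))
  if (length(qs) < 3) return(rep(1L, length(x)))   # constant feature
  cut(x, breaks = qs, include.lowest = TRUE, labels = FALSE)
}

mutual_information <- function(a, b) {
  tab <- table(a, b)
  p <- tab / sum(tab)
  px <- rowSums(p)
  py <- colSums(p)
  nz <- p > 0
  sum(p[nz] * log(p[nz] / outer(px, py)[nz]))
}

#' Minimum-redundancy maximum-relevance feature ranking
#'
#' Greedy mRMR (mutual-information difference criterion): features are
#' discretized by equal-frequency tertile binning; each step adds the
#' feature maximizing relevance to the label minus mean redundancy with the
#' already selected set.
#'
#' @param x numeric matrix/data.frame of features.
#' @param y class labels (two levels).
#' @param k number of features to rank.
#' @return character vector of the top-k feature names, with relevance
#'   scores in attribute `"relevance"`.
#' @export
mrmr_select <- function(x, y, k = min(10, ncol(x))) {
  x <- as.data.frame(x)
  if (length(unique(y)) < 2) stop("mRMR needs >= 2 classes")
  if (k > ncol(x)) stop("k exceeds the feature count")
  disc <- lapply(x, discretize_ef)
  rel <- vapply(disc, function(f) mutual_information(f, y), numeric(1))
  selected <- character(0)
  remaining <- names(x)
  red_cache <- matrix(NA_real_, ncol(x), ncol(x),
                      dimnames = list(names(x), names(x)))
  while (length(selected) < k) {
    score <- vapply(remaining, function(f) {
      if (length(selected) == 0) return(rel[[f]])
      reds <- vapply(selected, function(s) {
        if (is.na(red_cache[f, s])) {
          mi <- mutual_information(disc[[f]], disc[[s]])
          red_cache[f, s] <<- mi
          red_cache[s, f] <<- mi
        }
        red_cache[f, s]
      }, numeric(1))
      rel[[f]] - mean(reds)
    }, numeric(1))
    pick <- remaining[which.max(score)]
    selected <- c(selected, pick)
    remaining <- setdiff(remaining, pick)
  }
  attr(selected, "relevance") <- rel[selected]
  selected
}

# ---- classifiers -----------------------------------------------------------

rf_grow_tree <- function(X, y, mtry, min_node = 2, max_depth = 10) {
  grow <- function(rows, depth) {
    ys <- y[rows]
    p1 <- mean(ys)
    if (depth >= max_depth || length(rows) < 2 * min_node ||
        p1 == 0 || p1 == 1)
      return(list(leaf = TRUE, prob = p1))
    feats <- sample.int(ncol(X), mtry)
    best <- NULL
    base_gini <- p1 * (1 - p1)
    for (f in feats) {
      v <- X[rows, f]
      splits <- unique(quantile(v, probs = c(0.25, 0.5, 0.75), names = FALSE))
      for (s in splits) {
        left <- v <= s
        nl <- sum(left)
        if (nl < min_node || length(rows) - nl < min_node) next
        pl <- mean(ys[left])
        pr <- mean(ys[!left])
        g <- (nl * pl * (1 - pl) +
              (length(rows) - nl) * pr * (1 - pr)) / length(rows)
        if (is.null(best) || g < best$gini)
          best <- list(gini = g, feature = f, split = s)
      }
    }
    if (is.null(best) || best$gini >= base_gini - 1e-12)
      return(list(leaf = TRUE, prob = p1))
    v <- X[rows, best$feature]
    list(leaf = FALSE, feature = best$feature, split = best$split,
         left = grow(rows[v <= best$split], depth + 1),
         right = grow(rows[v > best$split], depth + 1))
  }
  grow(seq_len(nrow(X)), 0)
}

rf_predict_tree <- function(tree, X) {
  out <- numeric(nrow(X))
  walk <- function(node, rows) {
    if (length(rows) == 0) return()
    if (node$leaf) {
      out[rows] <<- node$prob
      return()
    }
    v <- X[rows, node$feature]
    walk(node$left, rows[v <= node$split])
    walk(node$right, rows[v > node$split])
  }
  walk(tree, seq_len(nrow(X)))
  out
}

#' Fit a classifier
#'
#' LDA and QDA via MASS (priors = class frequencies); `"rf"` is a compact
#' random forest (bootstrap resampling, gini CART with `sqrt(p)` candidate
#' features per split, 500 trees) implemented in-package since no forest
#' package is available in the target environment.
#'
#' @param X numeric matrix of features (rows = patients).
#' @param y labels (`"responder"` positive).
#' @param method `"lda"`, `"qda"` or `"rf"`.
#' @param seed seed for the forest.
#' @param ntree forest size.
#' @return classifier object for [predict_scores()].
#' @export
fit_classifier <- function(X, y, method = c("lda", "qda", "rf"), seed = 1L,
                           ntree = 500) {
  method <- match.arg(method)
  X <- as.matrix(X)
  yb <- as_binary_label(y)
  if (method %in% c("lda", "qda")) {
    # drop near-constant columns that would make covariance singular
    keep <- apply(X, 2, function(v) stats::var(v) > 1e-12)
    Xk <- X[, keep, drop = FALSE]
    fit <- if (method == "lda") MASS::lda(Xk, grouping = factor(yb))
           else MASS::qda(Xk, grouping = factor(yb))
    structure(list(method = method, fit = fit, keep = keep),
              class = "stodeo_classifier")
  } else {
    set.seed(seed)
    mtry <- max(1L, floor(sqrt(ncol(X))))
    trees <- vector("list", ntree)
    for (b in seq_len(ntree)) {
      rows <- sample.int(nrow(X), replace = TRUE)
      trees[[b]] <- rf_grow_tree(X[rows, , drop = FALSE], yb[rows], mtry)
    }
    structure(list(method = "rf", trees = trees), class = "stodeo_classifier")
  }
}

#' Predict positive-class scores
#'
#' @param model a [fit_classifier()] result.
#' @param X feature matrix.
#' @return numeric scores in `[0, 1]` (posterior probability of responder).
#' @export
predict_scores <- function(model, X) {
  X <- as.matrix(X)
  if (model$method %in% c("lda", "qda")) {
    p <- predict(model$fit, X[, model$keep, drop = FALSE])$posterior
    p[, "TRUE"]
  } else {
    rowMeans(vapply(model$trees, function(tr) rf_predict_tree(tr, X),
                    numeric(nrow(X))))
  }
}

# confusion metrics at a threshold; positive class = responder
confusion_metrics <- function(scores, labels, threshold) {
  y <- as_binary_label(labels)
  pred <- scores >= threshold
  tp <- sum(pred & y); fn <- sum(!pred & y)
  fp <- sum(pred & !y); tn <- sum(!pred & !y)
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  prec <- if (tp + fp > 0) tp / (tp + fp) else 0
  f1 <- if (prec + sens > 0) 2 * prec * sens / (prec + sens) else 0
  c(accuracy = (tp + tn) / length(y), sensitivity = sens, specificity = spec,
    f_score = f1, precision = prec, tp = tp, fp = fp, tn = tn, fn = fn)
}

youden_threshold <- function(scores, labels) {
  y <- as_binary_label(labels)
  cand <- sort(unique(scores))
  cand <- c(cand, max(cand) + 1e-9)
  j <- vapply(cand, function(th) {
    sens <- mean(scores[y] >= th)
    spec <- mean(scores[!y] < th)
    sens + spec - 1
  }, numeric(1))
  cand[which.max(j)]
}

stratified_folds <- function(labels, n_folds, seed) {
  y <- as_binary_label(labels)
  fold <- integer(length(y))
  set.seed(seed)
  for (cls in c(TRUE, FALSE)) {
    rows <- which(y == cls)
    fold[rows] <- sample(rep_len(seq_len(n_folds), length(rows)))
  }
  # guard: every fold must carry both classes
  for (attempt in 1:20) {
    ok <- all(vapply(seq_len(n_folds), function(f)
      length(unique(y[fold == f])) == 2, logical(1)))
    if (ok) break
    set.seed(seed + 1000 * attempt)
    for (cls in c(TRUE, FALSE)) {
      rows <- which(y == cls)
      fold[rows] <- sample(rep_len(seq_len(n_folds), length(rows)))
    }
  }
  fold
}

#' Repeated stratified cross-validation of a feature set
#'
#' Runs `n_runs` of `n_folds`-fold stratified cross-validation on the
#' discovery rows. Per fold, features are z-scored on the training fold,
#' mRMR ranks the training features, the top `n_select` train the
#' classifier, and out-of-fold scores are pooled. Per run, a bootstrapped
#' AUC is computed (median AUC over `n_boot` patient-level resamples of the
#' pooled scores) together with threshold metrics at the run's Youden point.
#' Reported values are means (SDs) across runs.
#'
#' @param table feature data.frame (must contain `label`).
#' @param features character vector of feature columns to consider.
#' @param classifier `"lda"`, `"qda"` or `"rf"`.
#' @param n_runs,n_folds repetition scheme (defaults 50 x 3).
#' @param n_select number of mRMR-selected features per fold.
#' @param n_boot bootstrap resamples per run.
#' @param seed integer seed; the full report is deterministic given it.
#' @return object of class `evaluation_report`: `auc_runs`, `metrics`
#'   (mean/sd per measure), `selection_frequency`, settings.
#' @export
run_cv <- function(table, features, classifier = c("lda", "qda", "rf"),
                   n_runs = 50, n_folds = 3, n_select = min(6, length(features)),
                   n_boot = 100, seed = 1L) {
  classifier <- match.arg(classifier)
  check_feature_table(table)
  y <- table$label
  if (length(unique(y)) < 2) stop("need both classes in the discovery rows")
  X <- as.matrix(table[, features, drop = FALSE])
  auc_runs <- numeric(n_runs)
  metric_runs <- matrix(NA_real_, n_runs, 5,
                        dimnames = list(NULL, c("accuracy", "sensitivity",
                                                "specificity", "f_score",
                                                "precision")))
  sel_count <- setNames(numeric(length(features)), features)
  n_fold_total <- 0
  for (r in seq_len(n_runs)) {
    rs <- seed + r * 131L
    fold <- stratified_folds(y, n_folds, rs)
    oof <- rep(NA_real_, nrow(X))
    for (f in seq_len(n_folds)) {
      tr <- fold != f
      mu <- colMeans(X[tr, , drop = FALSE])
      sg <- apply(X[tr, , drop = FALSE], 2, sd)
      sg[sg < 1e-12] <- 1
      Z <- sweep(sweep(X, 2, mu), 2, sg, "/")
      sel <- mrmr_select(Z[tr, , drop = FALSE], y[tr],
                         k = min(n_select, length(features)))
      sel_count[sel] <- sel_count[sel] + 1
      n_fold_total <- n_fold_total + 1
      mdl <- fit_classifier(Z[tr, sel, drop = FALSE], y[tr], classifier,
                            seed = rs + f)
      oof[!tr] <- predict_scores(mdl, Z[!tr, sel, drop = FALSE])
    }
    set.seed(rs + 7L)
    boot_aucs <- vapply(seq_len(n_boot), function(b) {
      rows <- sample.int(length(oof), replace = TRUE)
      if (length(unique(y[rows])) < 2) return(NA_real_)
      auc_score(oof[rows], y[rows])
    }, numeric(1))
    auc_runs[r] <- median(boot_aucs, na.rm = TRUE)
    th <- youden_threshold(oof, y)
    metric_runs[r, ] <- confusion_metrics(oof, y, th)[colnames(metric_runs)]
  }
  metrics <- rbind(mean = c(auc = mean(auc_runs), colMeans(metric_runs)),
                   sd = c(auc = sd(auc_runs), apply(metric_runs, 2, sd)))
  structure(list(auc_runs = auc_runs, metrics = metrics,
                 selection_frequency = sort(sel_count / n_fold_total,
                                            decreasing = TRUE),
                 classifier = classifier, n_runs = n_runs, n_folds = n_folds,
                 n_select = n_select, features = features, seed = seed),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> %s, %d x %d-fold CV\n", x$classifier,
              x$n_runs, x$n_folds))
  cat(sprintf("  AUC %.3f (%.3f)\n", x$metrics["mean", "auc"],
              x$metrics["sd", "auc"]))
  print(round(x$metrics, 3))
  invisible(x)
}

#' Compare feature-set reports on their per-run AUC distributions
#'
#' Kruskal-Wallis omnibus test across the per-run AUC vectors, with pairwise
#' Wilcoxon rank-sum post-hoc tests corrected by Holm's method. Significance
#' flags are emitted at the two reporting thresholds (0.05 and 0.02).
#'
#' @param reports named list of `evaluation_report`s (same `n_runs`).
#' @param thresholds reporting thresholds for the significance flags.
#' @return list with `omnibus_p`, `pairwise` (data.frame with raw and
#'   adjusted p plus flags).
#' @export
compare_feature_sets <- function(reports, thresholds = c(0.05, 0.02)) {
  stopifnot(length(reports) >= 2)
  runs <- vapply(reports, function(r) length(r$auc_runs), integer(1))
  if (length(unique(runs)) != 1) stop("reports have unequal run counts")
  if (is.null(names(reports)))
    names(reports) <- paste0("set", seq_along(reports))
  aucs <- lapply(reports, `[[`, "auc_runs")
  grp <- factor(rep(names(reports), each = runs[1]))
  omni <- kruskal.test(unlist(aucs), grp)$p.value
  prs <- utils::combn(names(reports), 2)
  pw <- data.frame(a = prs[1, ], b = prs[2, ], p = NA_real_)
  for (i in seq_len(ncol(prs)))
    pw$p[i] <- suppressWarnings(
      wilcox.test(aucs[[prs[1, i]]], aucs[[prs[2, i]]])$p.value)
  pw$p_adj <- p.adjust(pw$p, "holm")
  for (th in thresholds)
    pw[[sprintf("sig_%g", th)]] <- pw$p_adj <= th
  list(omnibus_p = omni, pairwise = pw)
}

#' Train a final model on the discovery cohort
#'
#' Standardizes on discovery statistics, selects `n_select` features by mRMR
#' on the full discovery rows, and fits the classifier; the returned model
#' carries the standardization so it can be applied to validation rows.
#'
#' @inheritParams run_cv
#' @return a `final_model` list.
#' @export
train_final_model <- function(table, features, classifier = c("lda", "qda", "rf"),
                              n_select = min(6, length(features)), seed = 1L) {
  classifier <- match.arg(classifier)
  X <- as.matrix(table[, features, drop = FALSE])
  mu <- colMeans(X)
  sg <- apply(X, 2, sd)
  sg[sg < 1e-12] <- 1
  Z <- sweep(sweep(X, 2, mu), 2, sg, "/")
  sel <- mrmr_select(Z, table$label, k = min(n_select, length(features)))
  mdl <- fit_classifier(Z[, sel, drop = FALSE], table$label, classifier,
                        seed = seed)
  structure(list(model = mdl, selected = sel, mu = mu, sigma = sg,
                 features = features, classifier = classifier),
            class = "final_model")
}

#' Hold-out evaluation of a trained model
#'
#' Scores the validation rows with a discovery-trained model; reports the
#' threshold-free AUC plus confusion metrics at the Youden-optimal threshold
#' chosen on the validation ROC (mirroring the published protocol, which is
#' optimistic by construction and documented as such).
#'
#' @param model a [train_final_model()] result.
#' @param validation validation feature data.frame.
#' @return list with `auc`, `threshold`, `metrics` (including the confusion
#'   counts) and `scores`.
#' @export
holdout_evaluate <- function(model, validation) {
  X <- as.matrix(validation[, model$features, drop = FALSE])
  Z <- sweep(sweep(X, 2, model$mu), 2, model$sigma, "/")
  scores <- predict_scores(model$model, Z[, model$selected, drop = FALSE])
  y <- validation$label
  if (length(unique(y)) < 2) stop("AUC undefined: single-class validation set")
  auc <- auc_score(scores, y)
  th <- youden_threshold(scores, y)
  list(auc = auc, threshold = th, metrics = confusion_metrics(scores, y, th),
       scores = scores)
}

#' Clinical baseline models
#'
#' Runs the same CV protocol on a clinical baseline: `"ctnm"` (clinical TNM
#' stage column) or `"wall_volume"` (annotated wall volume column).
#'
#' @param table feature data.frame containing the baseline column.
#' @param baseline `"ctnm"` or `"wall_volume"`.
#' @inheritParams run_cv
#' @return an `evaluation_report`.
#' @export
baseline_models <- function(table, baseline = c("ctnm", "wall_volume"),
                            classifier = "lda", n_runs = 50, n_folds = 3,
                            seed = 1L) {
  baseline <- match.arg(baseline)
  col <- if (baseline == "ctnm") "ctnm" else "wall_volume"
  if (!col %in% names(table)) stop("baseline column missing: ", col)
  tbl <- table
  tbl$baseline_value <- as.numeric(table[[col]])
  run_cv(tbl, "baseline_value", classifier, n_runs, n_folds, n_select = 1,
         seed = seed)
}

#' Subgroup robustness testing of top features
#'
#' Wilcoxon rank-sum test of each feature between the two groups of each
#' grouping variable (sex, field strength, annotation, institution,
#' scanner), with the Bonferroni threshold 0.05 / (features x groupings)
#' reported alongside raw p-values and group medians/IQRs.
#'
#' @param table feature data.frame with the grouping columns.
#' @param top_features character vector of feature columns.
#' @param groupings grouping column names present in `table`.
#' @return data.frame of feature, grouping, group sizes, medians, IQRs, p,
#'   `bonferroni_threshold`, `significant`, `underpowered`.
#' @export
robustness_tests <- function(table, top_features,
                             groupings = c("sex", "field_strength",
                                           "annotation", "institution",
                                           "scanner")) {
  groupings <- intersect(groupings, names(table))
  if (length(groupings) == 0) stop("no grouping columns present")
  bonf <- 0.05 / (length(top_features) * length(groupings))
  out <- list()
  for (g in groupings) {
    lv <- unique(table[[g]])
    if (length(lv) != 2) next
    a <- table[[g]] == lv[1]
    for (f in top_features) {
      xa <- table[[f]][a]
      xb <- table[[f]][!a]
      p <- if (length(unique(c(xa, xb))) == 1) 1
           else suppressWarnings(wilcox.test(xa, xb)$p.value)
      out[[length(out) + 1L]] <- data.frame(
        feature = f, grouping = g, group_a = lv[1], group_b = lv[2],
        n_a = sum(a), n_b = sum(!a),
        median_a = median(xa), iqr_a = stats::IQR(xa),
        median_b = median(xb), iqr_b = stats::IQR(xb),
        p = p, bonferroni_threshold = bonf, significant = p <= bonf,
        underpowered = min(sum(a), sum(!a)) < 3)
    }
  }
  do.call(rbind, out)
}

#' Instability score of features across acquisition groups
#'
#' A documented surrogate for the published 0-1 instability index (whose
#' exact formula is not public): each feature is rank-transformed and the
#' score is its between-group rank dispersion divided by the maximum
#' dispersion achievable for the observed group sizes, bounded in `[0, 1]`;
#' 0 = unaffected by acquisition differences, 1 = fully determined by them.
#'
#' @param table feature data.frame.
#' @param top_features feature columns to score.
#' @param acquisition_grouping grouping column (e.g., `"scanner"` or
#'   `"field_strength"`).
#' @return named numeric vector of scores with attribute
#'   `"surrogate" = TRUE`.
#' @export
instability_score <- function(table, top_features,
                              acquisition_grouping = "scanner") {
  g <- factor(table[[acquisition_grouping]])
  if (nlevels(g) < 2) stop("instability score needs >= 2 acquisition groups")
  n <- length(g)
  sizes <- tabulate(g)
  # maximum achievable between-group rank dispersion: groups occupying
  # contiguous rank blocks; normalizing by it makes a fully group-determined
  # feature score 1 (raw rank eta-squared saturates below 1)
  blocks <- c(0, cumsum(sizes))
  bm <- vapply(seq_along(sizes),
               function(k) (blocks[k] + blocks[k + 1] + 1) / 2, numeric(1))
  ssb_max <- sum(sizes * (bm - (n + 1) / 2)^2)
  out <- vapply(top_features, function(f) {
    r <- rank(table[[f]])
    gm <- tapply(r, g, mean)
    ssb <- sum(sizes * (gm - mean(r))^2)
    if (ssb_max < 1e-15) 0 else min(1, ssb / ssb_max)
  }, numeric(1))
  attr(out, "surrogate") <- TRUE
  out
}
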