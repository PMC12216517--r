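test_that("mRMR ranks planted informative features first and penalizes redundancy", {
  set.seed(1)
  n <- 120
  y <- rep(c("responder", "non-responder"), each = n / 2)
  x <- data.frame(
    label_copy = as.numeric(y == "responder") + rnorm(n, 0, 0.05),
    n1 = rnorm(n), n2 = rnorm(n), n3 = rnorm(n))
  expect_equal(mrmr_select(x, y, k = 1)[1], "label_copy")

  # two identical informative features: the duplicate is pushed below an
  # independent weaker-but-informative one
  set.seed(2)
  strong <- as.numeric(y == "responder") * 2 + rnorm(n, 0, 0.4)
  weak <- as.numeric(y == "responder") + rnorm(n, 0, 1.2)
  x2 <- data.frame(strong = strong, strong_dup = strong, weak = weak,
                   noise = rnorm(n))
  sel <- mrmr_select(x2, y, k = 3)
  expect_equal(sel[1], "strong")
  expect_lt(match("weak", sel), match("strong_dup", sel, nomatch = 4))

  # k = everything is a permutation of the feature names
  sel_all <- mrmr_select(x2, y, k = 4)
  expect_setequal(sel_all, names(x2))
  expect_error(mrmr_select(x2, y, k = 9), "exceeds")
  expect_error(mrmr_select(x2, rep("a", n), k = 1), "2 classes")
})

test_that("AUC and confusion metrics match hand computation", {
  scores <- c(0.9, 0.8, 0.3, 0.6, 0.2, 0.1)
  labels <- c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)
  # Mann-Whitney by hand: pairs where positive outranks negative
  expect_equal(auc_score(scores, labels), 8 / 9)
  expect_equal(auc_score(-scores, labels), 1 - 8 / 9)
  cm <- stodeo:::confusion_metrics(scores, labels, threshold = 0.5)
  expect_equal(unname(cm["tp"]), 2)
  expect_equal(unname(cm["fn"]), 1)
  expect_equal(unname(cm["fp"]), 1)
  expect_equal(unname(cm["tn"]), 2)
  expect_equal(unname(cm["accuracy"]), 4 / 6)
  expect_equal(unname(cm["sensitivity"]), 2 / 3)
  expect_equal(unname(cm["specificity"]), 2 / 3)
  expect_equal(unname(cm["precision"]), 2 / 3)
  expect_equal(unname(cm["f_score"]), 2 * (2 / 3) * (2 / 3) / (4 / 3))
  # the reported metrics must be re-derivable from the confusion counts
  expect_equal(unname(cm["accuracy"]),
               unname((cm["tp"] + cm["tn"]) / sum(cm[c("tp", "fp", "tn", "fn")])))
})

test_that("repeated CV separates separable classes and is null on noise", {
  tab <- separable_table(n = 48, delta = 3)
  feats <- setdiff(names(tab), c("id", "label"))
  rep1 <- run_cv(tab, feats, "lda", n_runs = 8, n_folds = 3, seed = 3)
  expect_gte(rep1$metrics["mean", "auc"], 0.99)

  set.seed(9)
  tabp <- tab
  tabp$label <- sample(tab$label)
  repn <- run_cv(tabp, feats, "lda", n_runs = 8, n_folds = 3, seed = 3)
  expect_true(repn$metrics["mean", "auc"] > 0.3 &&
              repn$metrics["mean", "auc"] < 0.7)

  # same seed reproduces the report bit-exactly
  rep2 <- run_cv(tab, feats, "lda", n_runs = 8, n_folds = 3, seed = 3)
  expect_identical(rep1$auc_runs, rep2$auc_runs)
  expect_identical(rep1$metrics, rep2$metrics)
})

test_that("QDA and the in-package random forest also separate planted classes", {
  tab <- separable_table(n = 60, delta = 3)
  feats <- c("sig1", "sig2", paste0("noise", 1:4))
  for (clf in c("qda", "rf")) {
    rep <- run_cv(tab, feats, clf, n_runs = 3, n_folds = 3, seed = 5,
                  n_boot = 50)
    expect_gte(rep$metrics["mean", "auc"], 0.9)
  }
})

test_that("no training-fold information leaks into discovery CV", {
  # a feature informative ONLY through validation rows must not lift
  # discovery CV performance
  tab <- separable_table(n = 48, delta = 0)      # pure noise discovery
  feats <- setdiff(names(tab), c("id", "label"))
  base <- run_cv(tab, feats, "lda", n_runs = 6, n_folds = 3, seed = 7)
  tab2 <- tab
  tab2$oracle_like <- rnorm(nrow(tab))           # unrelated to labels
  rep2 <- run_cv(tab2, c(feats, "oracle_like"), "lda", n_runs = 6,
                 n_folds = 3, seed = 7)
  expect_lt(abs(rep2$metrics["mean", "auc"] - base$metrics["mean", "auc"]),
            0.15)
  expect_lt(rep2$metrics["mean", "auc"], 0.75)
})

test_that("feature-set comparison flags shifted AUC distributions", {
  mkrep <- function(aucs) structure(list(auc_runs = aucs),
                                    class = "evaluation_report")
  set.seed(4)
  a <- pmin(1, 0.7 + rnorm(50, 0, 0.03))
  b <- a                                     # identical vectors
  cmp_same <- compare_feature_sets(list(a = mkrep(a), b = mkrep(b)))
  expect_gt(cmp_same$pairwise$p[1], 0.9)

  c2 <- pmin(1, a - 0.2)                     # clearly shifted
  cmp_shift <- compare_feature_sets(list(a = mkrep(a), c = mkrep(c2)))
  expect_lt(cmp_shift$pairwise$p_adj[1], 0.01)
  expect_lt(cmp_shift$omnibus_p, 0.01)

  # three groups, one shifted: omnibus significant, correct pair flagged
  cmp3 <- compare_feature_sets(list(a = mkrep(a), b = mkrep(b + rnorm(50, 0, 1e-6)),
                                    c = mkrep(c2)))
  expect_lt(cmp3$omnibus_p, 0.01)
  flagged <- cmp3$pairwise[cmp3$pairwise$sig_0.05, c("a", "b")]
  expect_true(all(apply(flagged, 1, function(r) "c" %in% r)))
  expect_error(compare_feature_sets(list(a = mkrep(a), b = mkrep(a[1:10]))),
               "unequal")
})

test_that("hold-out evaluation honors closed-form cases and the 2x2 table", {
  tab <- separable_table(n = 60, delta = 4)
  feats <- setdiff(names(tab), c("id", "label"))
  mdl <- train_final_model(tab, feats, "lda", seed = 1)
  val <- separable_table(n = 40, delta = 4, seed = 77)
  hv <- holdout_evaluate(mdl, val)
  expect_gte(hv$auc, 0.95)
  # metrics recompute from the exported confusion counts
  m <- hv$metrics
  expect_equal(unname(m["accuracy"]),
               unname((m["tp"] + m["tn"]) / sum(m[c("tp", "fp", "tn", "fn")])))
  prec <- m["tp"] / (m["tp"] + m["fp"])
  sens <- m["tp"] / (m["tp"] + m["fn"])
  expect_equal(unname(m["f_score"]), unname(2 * prec * sens / (prec + sens)))

  # single-class validation: AUC undefined
  val1 <- val[val$label == "responder", ]
  expect_error(holdout_evaluate(mdl, val1), "single-class")
})

test_that("clinical baselines behave as planted", {
  tab <- separable_table(n = 48, delta = 2)
  # uninformative wall volume: AUC near chance
  set.seed(5)
  tab$wall_volume <- rnorm(nrow(tab), 5000, 300)
  b0 <- baseline_models(tab, "wall_volume", n_runs = 6, seed = 2)
  expect_true(b0$metrics["mean", "auc"] < 0.7)
  # monotone-in-label wall volume: AUC near 1
  tab$wall_volume <- 5000 + 500 * (tab$label == "responder") +
    rnorm(nrow(tab), 0, 20)
  b1 <- baseline_models(tab, "wall_volume", n_runs = 6, seed = 2)
  expect_gte(b1$metrics["mean", "auc"], 0.95)
  expect_error(baseline_models(tab, "ctnm"), "missing")
})

test_that("robustness statistics have correct null and power behavior", {
  set.seed(6)
  n <- 80
  tab <- data.frame(label = rep(c("responder", "non-responder"), n / 2),
                    sex = rep(c("male", "female"), each = n / 2),
                    f_same = rnorm(n))
  tab$f_shift <- rnorm(n) + ifelse(tab$sex == "male", 0, 2)
  tab$f_const <- rep(1, n)
  rt <- robustness_tests(tab, c("f_same", "f_shift", "f_const"),
                         groupings = "sex")
  expect_equal(rt$p[rt$feature == "f_const"], 1)
  expect_gt(rt$p[rt$feature == "f_same"], 0.004)
  expect_lt(rt$p[rt$feature == "f_shift"], 0.004)
  expect_equal(unique(rt$bonferroni_threshold), 0.05 / 3)
})

test_that("the instability surrogate is bounded and hits its limits", {
  set.seed(7)
  n <- 80
  tab <- data.frame(scanner = rep(c("vendorA", "vendorB"), each = n / 2),
                    indep = rnorm(n))
  tab$determined <- as.numeric(tab$scanner == "vendorA") + rnorm(n, 0, 1e-6)
  s <- instability_score(tab, c("indep", "determined"), "scanner")
  expect_lt(s["indep"], 0.1)
  expect_gt(s["determined"], 0.9)
  expect_true(all(s >= 0 & s <= 1))
  expect_identical(s, instability_score(tab, c("indep", "determined"),
                                        "scanner"))
  tab1 <- tab; tab1$scanner <- "vendorA"
  expect_error(instability_score(tab1, "indep", "scanner"), ">= 2")
})
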