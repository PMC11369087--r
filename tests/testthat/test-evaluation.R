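test_that("stratified folds preserve class ratios within one instance", {
  labels <- rep(c(1L, 0L), c(153L, 250L))
  folds <- stratified_folds(labels, k = 10, seed = 71)
  expect_identical(sort(unique(folds)), 1:10)
  sizes <- table(folds)
  expect_true(all(sizes %in% c(40L, 41L)))
  pos_per_fold <- table(folds[labels == 1])
  expect_true(all(pos_per_fold %in% c(15L, 16L)))
  neg_per_fold <- table(folds[labels == 0])
  expect_true(all(neg_per_fold == 25L))
  # every instance in exactly one fold
  expect_identical(length(folds), 403L)
  # determinism and seed sensitivity
  expect_identical(folds, stratified_folds(labels, k = 10, seed = 71))
  expect_false(identical(folds, stratified_folds(labels, k = 10, seed = 72)))
})

test_that("small and degenerate fold requests behave as specified", {
  expect_setequal(stratified_folds(c(1, 1, 0, 0), k = 2, seed = 1), c(1, 2))
  f <- stratified_folds(c(1, 1, 0, 0), k = 2, seed = 1)
  expect_identical(sort(f[1:2]), 1:2)  # one positive per fold
  expect_identical(sort(f[3:4]), 1:2)
  expect_error(stratified_folds(rep(1, 10), k = 2), "both classes")
  expect_error(stratified_folds(c(1, 0, 0, 0, 0), k = 3), "fewer members")
})

test_that("confusion-count metrics implement the standard formulas", {
  perfect <- classification_metrics(tp = 10, tn = 10, fp = 0, fn = 0)
  expect_equal(as.numeric(perfect), c(1, 1, 1, 1, 1))
  # every prediction wrong on a balanced table: the formula gives mcc = -1
  worst <- classification_metrics(tp = 0, tn = 0, fp = 10, fn = 10)
  expect_equal(worst[["accuracy"]], 0)
  expect_equal(worst[["mcc"]], -1)
  expect_true("f1" %in% attr(worst, "degenerate"))
  # genuinely undefined denominators fall back to 0 and are flagged
  none_pred <- classification_metrics(tp = 0, tn = 10, fp = 0, fn = 10)
  expect_equal(none_pred[["precision"]], 0)
  expect_equal(none_pred[["mcc"]], 0)
  expect_true(all(c("precision", "mcc") %in% attr(none_pred, "degenerate")))
  # literal recomputation oracle
  tp <- 70; tn <- 90; fp <- 30; fn <- 10
  m <- classification_metrics(tp, tn, fp, fn)
  expect_equal(m[["accuracy"]], (70 + 90) / 200)
  expect_equal(m[["precision"]], 70 / 100)
  expect_equal(m[["recall"]], 70 / 80)
  expect_equal(m[["f1"]], 2 * (70 / 100) * (70 / 80) / (70 / 100 + 70 / 80))
  expect_equal(m[["mcc"]],
               (70 * 90 - 30 * 10) / sqrt(100 * 80 * 120 * 100))
})

test_that("metric identities hold across random confusion tables", {
  set.seed(73)
  for (i in 1:25) {
    cts <- sample(0:50, 4, replace = TRUE)
    m <- classification_metrics(cts[1], cts[2], cts[3], cts[4])
    expect_true(all(m[c("accuracy", "precision", "recall", "f1")] >= 0 &
                      m[c("accuracy", "precision", "recall", "f1")] <= 1))
    expect_gte(m[["mcc"]], -1); expect_lte(m[["mcc"]], 1)
    # f1 = harmonic mean of precision and recall where both defined
    if (m[["precision"]] + m[["recall"]] > 0)
      expect_equal(m[["f1"]],
                   2 * m[["precision"]] * m[["recall"]] /
                     (m[["precision"]] + m[["recall"]]))
    # class swap maps mcc -> mcc under (tp<->tn, fp<->fn)
    m_swap <- classification_metrics(cts[2], cts[1], cts[4], cts[3])
    expect_equal(m_swap[["mcc"]], m[["mcc"]])
  }
})

test_that("AUC equals the Mann-Whitney pair probability", {
  # perfectly separated
  expect_equal(auc_roc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  expect_equal(auc_roc(c(0.1, 0.2, 0.8, 0.9), c(1, 1, 0, 0)), 0)
  # ties count one half
  expect_equal(auc_roc(c(0.5, 0.5), c(1, 0)), 0.5)
  # brute-force all-pairs oracle on random score/label sets
  set.seed(74)
  for (i in 1:10) {
    scores <- round(stats::runif(20), 1)  # rounding forces ties
    labels <- sample(c(0, 1), 20, replace = TRUE)
    if (length(unique(labels)) < 2) next
    pos <- scores[labels == 1]; neg <- scores[labels == 0]
    wins <- 0
    for (p in pos) for (n in neg)
      wins <- wins + (p > n) + 0.5 * (p == n)
    expect_equal(auc_roc(scores, labels), wins / (length(pos) * length(neg)))
  }
  # large-n independence gives AUC near 1/2
  set.seed(75)
  s <- stats::runif(2000); l <- sample(c(0, 1), 2000, replace = TRUE)
  expect_lt(abs(auc_roc(s, l) - 0.5), 0.05)
  expect_error(auc_roc(c(1, 2), c(1, 1)), "both classes")
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(76)
  scores <- stats::rnorm(60)
  labels <- rep(c(0, 1), 30)
  expect_equal(auc_roc(scores, labels),
               as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE))))
})

test_that("cross-validation recovers planted signal and is reproducible", {
  peps <- generate_synthetic(60, 60, composition_shift = c(K = 2),
                             center_ty = FALSE, seed = 77)
  spec <- feature_spec("no_reduction", "counts", 1)
  rep1 <- run_cv(peps, spec, "logistic", k = 5, seed = 7)
  expect_gt(rep1$aggregate[["auc_roc"]], 0.9)
  expect_identical(nrow(rep1$per_fold), 5L)
  rep2 <- run_cv(peps, spec, "logistic", k = 5, seed = 7)
  expect_identical(rep1$per_fold, rep2$per_fold)
  expect_error(run_cv(peps, spec, "perceptron", k = 5), "unknown model")
  expect_error(run_cv(peps, spec, "lgbm", k = 5), "not available")
})

test_that("tree and kernel classifiers run through the same harness", {
  peps <- generate_synthetic(40, 40, composition_shift = c(K = 2.5),
                             center_ty = FALSE, seed = 78)
  spec <- feature_spec("hydro", "counts", 1)
  for (model in c("rf", "xgb", "svm", "ann")) {
    rep <- run_cv(peps, spec, model, k = 3, seed = 8)
    expect_true(all(is.finite(rep$aggregate)))
    expect_gt(rep$aggregate[["auc_roc"]], 0.7)
  }
})

test_that("embedding-backed CV retrains representations per fold", {
  peps <- generate_synthetic(15, 15, seed = 79)
  spec <- feature_spec("hydro", "pro2vec", 1,
                       embedding_config = list(hydro = list(dimension = 8)))
  rep <- run_cv(peps, spec, "rf", k = 3, seed = 9)
  expect_identical(nrow(rep$per_fold), 3L)
  expect_true(all(is.finite(rep$aggregate)))
})

test_that("report rows mirror the results-table layout", {
  peps <- generate_synthetic(30, 30, composition_shift = c(K = 2),
                             center_ty = FALSE, seed = 80)
  spec <- feature_spec(c("no_reduction", "hydro"), c("counts", "tfeat"), c(1, 3))
  row <- report_row(run_cv(peps, spec, "logistic", k = 3, seed = 10))
  expect_identical(names(row),
                   c("Model", "Representations", "Feat_types", "Offsets",
                     "Nfeat", "Accuracy", "Precision", "Recall", "F1_score",
                     "AUC_ROC", "MCC"))
  expect_identical(row$Nfeat, 45L)
  expect_identical(row$Representations, "no_reduction,hydro")
})

test_that("stratified hold-out split respects the requested fraction", {
  labels <- rep(c(1L, 0L), c(50L, 100L))
  test <- train_test_split(labels, 0.2, seed = 81)
  expect_identical(sum(test[labels == 1]), 10L)
  expect_identical(sum(test[labels == 0]), 20L)
  expect_identical(test, train_test_split(labels, 0.2, seed = 81))
})
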