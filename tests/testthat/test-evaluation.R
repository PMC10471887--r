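test_that("confusion counts match per-sample enumeration", {
  truth <- c(rep("malignant", 3), rep("benign", 2))
  expect_equal(confusion_counts(truth, truth),
               c(TP = 3L, FP = 0L, TN = 2L, FN = 0L))
  # hand-built 8-sample set: TP=3, FN=1, TN=2, FP=2
  t8 <- c("malignant", "malignant", "malignant", "malignant",
          "benign", "benign", "benign", "benign")
  p8 <- c("malignant", "malignant", "malignant", "benign",
          "benign", "benign", "malignant", "malignant")
  cm <- confusion_counts(t8, p8)
  brute <- table(truth = t8, pred = p8)
  expect_equal(cm[["TP"]], brute["malignant", "malignant"])
  expect_equal(cm[["FN"]], brute["malignant", "benign"])
  expect_equal(cm[["TN"]], brute["benign", "benign"])
  expect_equal(cm[["FP"]], brute["benign", "malignant"])
  all_mal <- confusion_counts(rep("malignant", 4),
                              c("malignant", "benign", "malignant", "benign"))
  expect_equal(all_mal[["TN"]] + all_mal[["FP"]], 0L)
})

test_that("metric suite reproduces hand-worked values", {
  t8 <- c(rep("malignant", 4), rep("benign", 4))
  p8 <- c("malignant", "malignant", "malignant", "benign",
          "benign", "benign", "malignant", "malignant")
  s8 <- ifelse(p8 == "malignant", 0.9, 0.1)
  rep8 <- compute_metrics(data.frame(truth = t8, pred = p8, score = s8))
  expect_equal(rep8$sn, 0.75)
  expect_equal(rep8$sp, 0.5)
  expect_equal(rep8$acc, 0.625)
  # malignant F1 = 2/3, benign F1 = 4/7, macro = 13/21
  expect_equal(rep8$f1_macro, 13 / 21, tolerance = 1e-12)

  perfect <- data.frame(truth = t8, pred = t8,
                        score = ifelse(t8 == "malignant", 0.9, 0.1))
  repp <- compute_metrics(perfect)
  expect_equal(repp$acc, 1); expect_equal(repp$f1_macro, 1)
  expect_equal(repp$sn, 1); expect_equal(repp$sp, 1)
  expect_equal(repp$auc, 1)
})

test_that("the four-pair AUC example gives three quarters", {
  score <- c(0.9, 0.8, 0.85, 0.1)
  truth <- c("malignant", "malignant", "benign", "benign")
  expect_equal(auc_roc(score, truth), 3 / 4)
  expect_equal(auc_mann_whitney(score, truth), 3 / 4)
})

test_that("trapezoidal ROC area equals the Mann-Whitney oracle", {
  set.seed(123)
  for (rep in 1:200) {
    preds <- random_prediction_set(sample(5:40, 1))
    expect_equal(auc_roc(preds$score, preds$truth),
                 auc_mann_whitney(preds$score, preds$truth),
                 tolerance = 1e-12)
  }
})

test_that("AUC agrees with an external reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(321)
  for (rep in 1:20) {
    preds <- random_prediction_set(sample(8:50, 1))
    ref <- as.numeric(pROC::auc(pROC::roc(
      response = preds$truth, predictor = preds$score,
      levels = c("benign", "malignant"), direction = "<", quiet = TRUE)))
    expect_equal(auc_roc(preds$score, preds$truth), ref, tolerance = 1e-12)
  }
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(55)
  preds <- random_prediction_set(30)
  a <- auc_roc(preds$score, preds$truth)
  expect_equal(auc_roc(preds$score^3, preds$truth), a, tolerance = 1e-12)
  expect_equal(auc_roc(plogis(5 * preds$score - 2), preds$truth), a,
               tolerance = 1e-12)
})

test_that("swapping class roles exchanges sensitivity and specificity", {
  set.seed(66)
  preds <- random_prediction_set(40)
  rep1 <- compute_metrics(preds)
  flip <- function(z) ifelse(z == "malignant", "benign", "malignant")
  rep2 <- compute_metrics(data.frame(truth = flip(preds$truth),
                                     pred = flip(preds$pred),
                                     score = 1 - preds$score))
  expect_equal(rep1$sn, rep2$sp)
  expect_equal(rep1$sp, rep2$sn)
  expect_equal(rep1$acc, rep2$acc)
  expect_equal(rep1$auc, rep2$auc, tolerance = 1e-12)
})

test_that("degenerate single-class folds flag undefined metrics", {
  one_class <- data.frame(truth = rep("malignant", 5),
                          pred = rep("malignant", 5), score = runif(5))
  w <- capture_warnings(rep1 <- compute_metrics(one_class))
  expect_true(any(grepl("specificity undefined", w)))
  expect_true(any(grepl("AUC undefined", w)))
  expect_true(is.na(rep1$auc))
  expect_true(is.na(rep1$sp))
  expect_equal(rep1$sn, 1)
})

test_that("aggregation emits both mean-of-folds and pooled modes", {
  mk <- function(acc_n, n = 10) {
    n_correct <- round(acc_n * n)
    truth <- rep(c("malignant", "benign"), n / 2)
    pred <- truth
    if (n_correct < n) pred[seq_len(n - n_correct)] <-
        ifelse(truth[seq_len(n - n_correct)] == "malignant",
               "benign", "malignant")
    compute_metrics(data.frame(truth = truth, pred = pred,
                               score = ifelse(pred == "malignant", .9, .1)))
  }
  agg_same <- aggregate_metrics(list(mk(0.9), mk(0.9)))
  expect_equal(agg_same$mean$acc, 0.9)
  agg <- aggregate_metrics(list(mk(0.9), mk(1.0)))
  expect_equal(agg$mean$acc, 0.95)
  # pooled and mean disagree on imbalanced folds: 8/10 plus 30/30 correct
  r1 <- mk(0.8, 10); r2 <- mk(1.0, 30)
  agg2 <- aggregate_metrics(list(r1, r2))
  expect_equal(agg2$mean$acc, (0.8 + 1.0) / 2)
  expect_equal(agg2$pooled$acc, 38 / 40)
})
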