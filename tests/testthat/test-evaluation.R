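test_that("confusion metrics reproduce the worked screening example", {
  cm <- confusion_from_counts(160, 155, 40, 35)
  expect_identical(cm$tp, 35)
  expect_identical(cm$fn, 5)
  expect_identical(cm$fp, 5)
  m <- confusion_metrics(cm)
  expect_equal(m$recall, 0.875)
  expect_equal(m$accuracy, 0.95)
  expect_equal(m$precision, 0.875)
  expect_equal(m$specificity, 155 / 160)
})

test_that("degenerate confusion matrices give NA metrics, not errors", {
  perfect <- confusion_metrics(confusion_matrix(10, 0, 0, 30))
  expect_equal(unlist(perfect), c(accuracy = 1, precision = 1, recall = 1,
                                  specificity = 1, f1 = 1))
  no_pos_calls <- confusion_metrics(confusion_matrix(0, 0, 5, 10))
  expect_true(is.na(no_pos_calls$precision))
  expect_equal(no_pos_calls$recall, 0)
  expect_error(confusion_matrix(-1, 0, 0, 0), "nonnegative")
})

test_that("AUC equals the concordance probability", {
  expect_equal(roc_auc(c(1, 2, 3, 10), c(0, 0, 1, 1))$auc, 1.0)
  # 4 samples: brute force over the 2x2 positive/negative pairs gives 3/4
  expect_equal(roc_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))$auc, 0.75)
  expect_error(roc_auc(c(1, 2), c(1, 1)), "both classes")
  set.seed(41)
  scores <- runif(10000)
  labels <- rbinom(10000, 1, 0.5)
  expect_equal(roc_auc(scores, labels)$auc, 0.5, tolerance = 0.02)
  # invariance under strictly monotone transforms + monotone curve
  r1 <- roc_auc(scores[1:500], labels[1:500])
  r2 <- roc_auc(qlogis(scores[1:500]), labels[1:500])
  expect_equal(r1$auc, r2$auc)
  expect_true(all(diff(r1$roc_points$fpr) >= 0))
  expect_true(all(diff(r1$roc_points$tpr) >= 0))
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(42)
  scores <- c(rnorm(60, 1), rnorm(90, 0))
  labels <- c(rep(1, 60), rep(0, 90))
  ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE)))
  expect_equal(roc_auc(scores, labels)$auc, ref, tolerance = 1e-10)
})

test_that("net benefit follows the printed decision-analytic formula", {
  for (thr in c(0.01, 0.1, 0.25)) {
    expect_equal(net_benefit(1, 1, 0.2, thr), 0.2)
  }
  expect_equal(net_benefit(0.875, 0.96875, 0.2, 0.05),
               0.875 * 0.2 - (1 - 0.96875) * 0.8 * (0.05 / 0.95))
  # treat-all reference crosses zero where threshold equals prevalence
  expect_equal(net_benefit(1, 0, 0.2, 0.2), 0)
  expect_error(net_benefit(0.9, 0.9, 0.2, 1), "threshold")
  expect_error(net_benefit(0.9, 0.9, 1.2, 0.1), "prevalence")
})

test_that("decision curves match pointwise recomputation", {
  set.seed(5)
  scores <- runif(300)
  labels <- rbinom(300, 1, 0.3)
  dca <- dca_curve(scores, labels)
  expect_equal(dca$threshold, seq(0.01, 0.30, by = 0.01))
  expect_true(all(dca$treat_none == 0))
  for (i in c(1, 10, 30)) {
    thr <- dca$threshold[i]
    pred <- scores >= thr
    sens <- sum(pred & labels == 1) / sum(labels == 1)
    spec <- sum(!pred & labels == 0) / sum(labels == 0)
    expect_equal(dca$net_benefit[i], net_benefit(sens, spec, 0.2, thr))
    expect_equal(dca$treat_all[i], net_benefit(1, 0, 0.2, thr))
  }
})

test_that("stratified folds preserve class balance and partition indices", {
  labels <- c(rep(0L, 160), rep(1L, 40))
  folds <- stratified_kfold(labels, k = 5, seed = 3)
  expect_length(folds, 5)
  for (f in folds) {
    expect_identical(sum(labels[f] == 1L), 8L)
    expect_identical(length(f), 40L)
  }
  expect_identical(sort(unlist(folds)), 1:200)
  expect_identical(anyDuplicated(unlist(folds)), 0L)
  expect_identical(folds, stratified_kfold(labels, k = 5, seed = 3))
  expect_false(identical(folds, stratified_kfold(labels, k = 5, seed = 4)))
  # forced stratification at the smallest size
  tiny <- stratified_kfold(c(0, 0, 1, 1), k = 2, seed = 1)
  for (f in tiny) expect_identical(length(unique(c(0, 0, 1, 1)[f])), 2L)
  expect_error(stratified_kfold(c(0, 0, 0, 1), k = 2), "at least k")
})

test_that("one-way ANOVA matches the hand-computed F ratio", {
  res <- one_way_anova(list(c(1, 2, 3), c(2, 3, 4), c(3, 4, 5)))
  expect_equal(res$F, 3.0)
  expect_equal(res$df1, 2)
  expect_equal(res$df2, 6)
  expect_equal(res$p, stats::pf(3, 2, 6, lower.tail = FALSE))
  same <- one_way_anova(list(c(1, 2), c(1, 2), c(1, 2)))
  expect_equal(same$F, 0)
  flat <- one_way_anova(list(c(1, 1), c(1, 1)))
  expect_equal(flat$F, 0)
  expect_error(one_way_anova(list(c(1, 2))), "2 groups")
})

test_that("two-group Tukey HSD collapses to the pooled t-test", {
  set.seed(13)
  g1 <- rnorm(12)
  g2 <- rnorm(12, 0.8)
  tk <- tukey_hsd(list(a = g1, b = g2))
  tt <- stats::t.test(g2, g1, var.equal = TRUE)
  expect_equal(tk$p_adj, tt$p.value, tolerance = 1e-8)
  none <- tukey_hsd(list(a = c(1, 2, 3), b = c(1, 2, 3)))
  expect_false(any(none$significant))
})

test_that("Tukey HSD flags exactly the separated group", {
  set.seed(29)
  groups <- list(a = rnorm(20, 0), b = rnorm(20, 0), c = rnorm(20, 10))
  tk <- tukey_hsd(groups, alpha = 0.05)
  flagged <- tk$pair[tk$significant]
  expect_setequal(flagged, c("c-a", "c-b"))
})

test_that("model evaluation aggregates greedy rollouts coherently", {
  ds <- fixture_dataset(4)
  # constant classifier: always calls class 1 (benign)
  model <- rig_model(biases = c(0, 0, 0, 0, 5, -5))
  res <- evaluate_model(model, ds)
  expect_equal(res$metrics$recall, 0)
  expect_equal(res$metrics$specificity, 1)
  expect_identical(res$confusion$tp + res$confusion$fn, 4)
  # DCA rows reproduce the net-benefit formula on the evaluated scores
  pos <- res$predictions$truth == 2
  for (i in c(3, 20)) {
    thr <- res$dca$threshold[i]
    pred <- res$predictions$score >= thr
    sens <- sum(pred & pos) / sum(pos)
    spec <- sum(!pred & !pos) / sum(!pos)
    expect_equal(res$dca$net_benefit[i], net_benefit(sens, spec, 0.2, thr))
  }
  expect_error(evaluate_model(model, list()), "empty")
})
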