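test_that("stratified folds balance both classes to within one record", {
  y <- factor(rep(c("RD", "NRO"), each = 90L), levels = c("RD", "NRO"))
  f <- stratified_folds(y, k = 10L, seed = 1L)
  for (k in 1:10) {
    expect_equal(as.vector(table(y[f == k])), c(9L, 9L))
  }
  y2 <- factor(rep(c("RD", "PSY"), c(42L, 38L)), levels = c("RD", "PSY"))
  f2 <- stratified_folds(y2, k = 10L, seed = 2L)
  tab <- table(f2, y2)
  expect_true(all(tab[, "PSY"] %in% 3:4))
  expect_true(all(tab[, "RD"] %in% 4:5))
  expect_equal(sort(unique(f2)), 1:10)
  expect_length(f2, 80L)
  expect_error(stratified_folds(factor(rep(c("a", "b"), c(5L, 90L))), k = 10L),
               "stratification error")
  expect_identical(stratified_folds(y, 10L, seed = 9L),
                   stratified_folds(y, 10L, seed = 9L))
})

test_that("sensitivity and specificity reproduce the published confusion-matrix arithmetic", {
  expect_equal(truncate_pct(sensitivity(confusion_matrix(TP = 79, FN = 11, FP = 12, TN = 78))), 87.7)
  expect_equal(truncate_pct(sensitivity(confusion_matrix(TP = 84, FN = 6, FP = 11, TN = 79))), 93.3)
  expect_equal(truncate_pct(specificity(confusion_matrix(TP = 79, FN = 11, FP = 12, TN = 78))), 86.6)
  expect_equal(truncate_pct(specificity(confusion_matrix(TP = 36, FN = 6, FP = 6, TN = 32))), 84.2)
  expect_equal(sensitivity(confusion_matrix(TP = 10, FN = 0, FP = 3, TN = 7)), 100)
  expect_equal(specificity(confusion_matrix(TP = 1, FN = 1, FP = 5, TN = 0)), 0)
  expect_error(sensitivity(confusion_matrix(TP = 0, FN = 0, FP = 1, TN = 1)),
               "undefined")
  expect_error(specificity(confusion_matrix(TP = 1, FN = 1, FP = 0, TN = 0)),
               "undefined")
  # reporting truncates, never rounds
  expect_equal(truncate_pct(87.78), 87.7)
  expect_equal(truncate_pct(93.29999), 93.2)
})

test_that("confusion counts are conserved and recomputable", {
  truth <- c(rep(TRUE, 6L), rep(FALSE, 4L))
  pred <- c(rep(TRUE, 5L), FALSE, TRUE, rep(FALSE, 3L))
  cm <- confusion_matrix(truth, pred)
  expect_equal(cm$TP + cm$FN + cm$FP + cm$TN, 10L)
  expect_equal(cm$TP + cm$FN, sum(truth))
  expect_equal(cm$FP + cm$TN, sum(!truth))
  expect_equal(sensitivity(cm), 100 * cm$TP / (cm$TP + cm$FN))
})

test_that("AUC equals the exhaustive pair-counting oracle", {
  # fixed 6-point toy case with a tie across classes
  truth <- c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)
  scores <- c(0.9, 0.6, 0.4, 0.6, 0.3, 0.1)
  expect_equal(roc_auc(truth, scores)$auc, auc_oracle(truth, scores))
  # by hand: 3 + (2 + 0.5 tie) + 2 concordant of 9 pairs
  expect_equal(auc_oracle(truth, scores), 7.5 / 9)
  # perfectly separated and anti-separated extremes
  expect_equal(roc_auc(c(TRUE, TRUE, FALSE), c(.9, .8, .1))$auc, 1)
  expect_equal(roc_auc(c(TRUE, TRUE, FALSE), c(.1, .2, .9))$auc, 0)
  # independent scores: AUC near 1/2 at large n
  set.seed(42L)
  tr <- rep(c(TRUE, FALSE), each = 2000L)
  sc <- stats::runif(4000L)
  expect_lt(abs(roc_auc(tr, sc)$auc - 0.5), 0.03)
  expect_error(roc_auc(c(TRUE, TRUE), c(.1, .2)), "both classes")
  # agreement with an established ROC implementation
  expect_equal(roc_auc(truth, scores)$auc,
               as.numeric(pROC::auc(pROC::roc(truth, scores, quiet = TRUE,
                                              direction = "<"))))
})

test_that("AUC matches the oracle on randomized small score lists with heavy ties", {
  set.seed(7L)
  for (i in 1:200) {
    n <- sample(3:12, 1L)
    truth <- c(TRUE, FALSE, sample(c(TRUE, FALSE), n - 2L, replace = TRUE))
    scores <- sample(seq(0, 1, by = 0.25), n, replace = TRUE)
    expect_equal(roc_auc(truth, scores)$auc, auc_oracle(truth, scores),
                 tolerance = 1e-12)
  }
})

test_that("the aggregation rule is the truncated mean of the three subset sensitivities", {
  expect_equal(aggregate_sensitivity(c(87.7, 93.3, 85.7)), 88.9)
  expect_equal(aggregate_sensitivity(c(77.3, 77.3, 77.3)), 77.3)
  expect_equal(aggregate_sensitivity(c(0, 0, 0)), 0)
  expect_error(aggregate_sensitivity(c(90, 90)), "three")
})

test_that("cross-validation conserves counts and nails a separable cohort", {
  ds <- simulate_paired_dataset(0.9, 30L, 30L, seed = 6L)
  rep <- cross_validate(ds, k = 5L, k_inner = 3L, seed = 6L)
  for (r in rep$results) {
    expect_equal(r$cm$TP + r$cm$FN + r$cm$FP + r$cm$TN, 60L,
                 label = r$classifier)
  }
  expect_equal(rep$results$FUSION$sensitivity, 100)
  expect_equal(rep$results$FUSION$specificity, 100)
  expect_equal(rep$results$FUSION$auc, 1)
  # stored percentages always recompute from the stored matrices
  for (r in rep$results) {
    expect_equal(r$sensitivity_reported, truncate_pct(sensitivity(r$cm)))
    expect_equal(r$specificity_reported, truncate_pct(specificity(r$cm)))
  }
  # per-fold sensitivities stored alongside pooled counts
  expect_length(rep$results$FUSION$fold_sensitivity, 5L)
})

test_that("the probability-triple suggestion rule matches its documented cases", {
  s <- rdscreen:::triple_suggestion(c(0.40, 0.76, 0.79))
  expect_equal(s$type, "RD")
  expect_equal(s$subset, 3L)
  expect_equal(s$probability, 0.79)
  s2 <- rdscreen:::triple_suggestion(c(0.06, 0.2, 0.3))
  expect_equal(s2$type, "NRO")
  expect_equal(s2$probability, 0.94)
  s3 <- rdscreen:::triple_suggestion(c(0.3, 0.08, 0.3))
  expect_equal(s3$type, "CD")
  expect_equal(s3$probability, 0.92)
  # boundary ties are resolved towards the rare-disease alarm
  s4 <- rdscreen:::triple_suggestion(c(0.5, 0.5, 0.5))
  expect_equal(s4$type, "RD")
})

test_that("evaluate_questionnaire routes a questionnaire through all three models", {
  models <- lapply(1:3, function(i) {
    train_fusion(simulate_paired_dataset(0.8, 20L, 20L, seed = 50L + i,
                                         subset_id = i,
                                         class_labels = c(paste0("RD", i),
                                                          c("NRO", "CD", "PSY")[i])),
                 k_inner = 3L, seed = 50L + i)
  })
  case <- make_records(1L, answer = 4L, group = "RD", diagnosis = "PAH")
  for (it in items[21:53]) case[[it]] <- 2L  # unaffected items near base
  tr <- evaluate_questionnaire(case, models)
  expect_length(tr$p_rd, 3L)
  expect_true(all(tr$p_rd >= 0 & tr$p_rd <= 1))
  expect_identical(tr$alt_labels, c("NRO", "CD", "PSY"))
  expect_error(evaluate_questionnaire(case, models[1:2]), "three")
})
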