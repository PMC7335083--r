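# SVM detection, metrics, RSI severity bins and the BPNN grader.

test_that("balanced_subsample downsamples the majority class 1:1", {
  co <- make_feature_cohort(n_lpr = 106, n_non = 246, seed = 2)
  bal <- balanced_subsample(co$features, co$labels, seed = 2)
  expect_equal(unname(table(bal$labels)), c(106L, 106L), ignore_attr = TRUE)
  bal2 <- balanced_subsample(co$features, co$labels, seed = 2)
  expect_identical(bal$indices, bal2$indices)
  even <- balanced_subsample(co$features[1:20, ], co$labels[c(1:10, 107:116)],
                             seed = 1)
  expect_equal(unname(table(even$labels)), c(10L, 10L), ignore_attr = TRUE)
  expect_error(balanced_subsample(co$features, rep("LPR", 352)),
               class = "lq_invalid_input")
})

test_that("compute_metrics matches hand counts and its identities", {
  truth <- c("non-LPR", "non-LPR", "non-LPR", "LPR", "LPR", "LPR")
  pred <- c("non-LPR", "non-LPR", "non-LPR", "non-LPR", "LPR", "LPR")
  m <- compute_metrics(pred, truth)
  expect_equal(c(m$TP, m$TN, m$FP, m$FN), c(3L, 2L, 1L, 0L))
  expect_equal(m$accuracy, 100 * 5 / 6, tolerance = 1e-9)
  expect_equal(m$sensitivity, 100)
  expect_equal(m$false_positive_rate, 100 / 3, tolerance = 1e-9)
  perfect <- compute_metrics(truth, truth)
  expect_equal(perfect$accuracy, 100)
  expect_equal(perfect$false_positive_rate, 0)
  expect_error(compute_metrics(pred[1:3], truth), class = "lq_invalid_input")
})

test_that("metric identities hold for random confusion tables", {
  set.seed(5)
  for (i in 1:20) {
    truth <- sample(c("LPR", "non-LPR"), 40, replace = TRUE, prob = c(0.4, 0.6))
    pred <- sample(c("LPR", "non-LPR"), 40, replace = TRUE)
    m <- compute_metrics(pred, truth)
    expect_equal(m$accuracy, 100 * (m$TP + m$TN) / (m$TP + m$TN + m$FP + m$FN))
    if (m$TP + m$FN > 0) expect_equal(m$sensitivity, 100 * m$TP / (m$TP + m$FN))
    if (m$FP + m$TN > 0)
      expect_equal(m$false_positive_rate, 100 * m$FP / (m$FP + m$TN))
    expect_equal(m$TP + m$TN + m$FP + m$FN, 40L)
  }
})

test_that("the SVM separates a strong synthetic cohort and not a permuted one", {
  sel <- lq_selected_features()
  co <- make_feature_cohort(n_lpr = 100, n_non = 100, effect = 3, seed = 11)
  cv <- svm_cv(co$features[, sel], co$labels, seed = 11)
  expect_gte(cv$accuracy, 95)
  perm <- local({ set.seed(42); sample(co$labels) })
  cv0 <- svm_cv(co$features[, sel], perm, seed = 11)
  expect_gte(cv0$accuracy, 40)
  expect_lte(cv0$accuracy, 60)
})

test_that("svm_cv is deterministic per seed", {
  sel <- lq_selected_features()
  co <- make_feature_cohort(n_lpr = 40, n_non = 40, effect = 2, seed = 3)
  a <- svm_cv(co$features[, sel], co$labels, seed = 7)
  b <- svm_cv(co$features[, sel], co$labels, seed = 7)
  expect_identical(a$per_fold, b$per_fold)
  expect_error(svm_cv(co$features[1:12, sel], co$labels[1:12], k = 10),
               class = "lq_invalid_input")
})

test_that("severity bins partition [13, 45] exactly as printed", {
  sev <- rsi_to_severity(13:45)
  expected <- c(rep("primary", 8), rep("intermediate", 10), rep("severe", 15))
  expect_identical(as.character(sev), expected)
  expect_identical(as.character(rsi_to_severity(c(13, 21, 45))),
                   c("primary", "intermediate", "severe"))
  expect_error(rsi_to_severity(12), class = "lq_out_of_range")
  expect_error(rsi_to_severity(46), class = "lq_out_of_range")
})

test_that("the BPNN fits separable clusters and trains deterministically", {
  # sep = 8 sd: cluster overlap is negligible, so perfect training fit
  sev <- make_severity_cohort(sep = 8, seed = 1)
  cfg <- severity_config(seed = 1)
  net <- bpnn_train(sev$features, sev$severity, cfg)
  expect_equal(mean(predict(net, sev$features) == sev$severity), 1)
  # loss settles: non-increasing over the trailing 50 epochs
  expect_true(all(diff(utils::tail(net$loss, 50)) <= 1e-6))
  net2 <- bpnn_train(sev$features, sev$severity, cfg)
  expect_identical(net$W1, net2$W1)
  expect_identical(net$W2, net2$W2)
  expect_error(severity_config(epochs = 0), class = "lq_invalid_input")
  expect_error(bpnn_train(sev$features, factor(rep("primary", nrow(sev$features)),
                                               levels = "primary"), cfg),
               class = "lq_invalid_input")
})

test_that("stratified CV grades a separable severity cohort well", {
  sev <- make_severity_cohort(seed = 5)
  cv <- stratified_cv(sev$features, sev$severity, severity_config(seed = 5))
  expect_gte(cv$accuracy, 90)
  expect_length(cv$per_fold, 10)
  # permuted labels fall to roughly the majority-class rate
  perm <- local({ set.seed(6); sample(sev$severity) })
  cv0 <- stratified_cv(sev$features, perm, severity_config(seed = 5))
  expect_lt(cv0$accuracy, 75)
  expect_error(stratified_cv(sev$features[1:4, ], sev$severity[c(1, 39, 93, 94)],
                             severity_config()),
               class = "lq_invalid_input")
})

test_that("detector accuracy is monotone in the planted effect size", {
  sel <- lq_selected_features()
  acc <- vapply(c(0, 1, 2, 3), function(e) {
    co <- make_feature_cohort(n_lpr = 60, n_non = 60, effect = e, seed = 17)
    svm_cv(co$features[, sel], co$labels, k = 5, seed = 17)$accuracy
  }, numeric(1))
  expect_true(all(diff(acc) >= 0))
})
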