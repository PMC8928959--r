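test_that("confusion counts partition the samples", {
  cc <- confusion_counts(c(1, 1, 0, 0), c(1, 0, 0, 1))
  expect_equal(unclass(cc), c(TP = 1L, FP = 1L, TN = 1L, FN = 1L),
               ignore_attr = TRUE)

  truth <- c(1, 0, 1, 1, 0)
  cc <- confusion_counts(truth, truth)
  expect_equal(cc[["FP"]], 0L)
  expect_equal(cc[["FN"]], 0L)

  set.seed(2)
  truth <- sample(0:1, 500, replace = TRUE)
  pred <- sample(0:1, 500, replace = TRUE)
  tally <- c(TP = 0L, FP = 0L, TN = 0L, FN = 0L)
  for (i in seq_along(truth)) {  # brute-force per-sample tally
    key <- if (truth[i] == 1 && pred[i] == 1) "TP"
      else if (truth[i] == 0 && pred[i] == 1) "FP"
      else if (truth[i] == 0 && pred[i] == 0) "TN" else "FN"
    tally[key] <- tally[key] + 1L
  }
  expect_equal(unclass(confusion_counts(truth, pred)), tally, ignore_attr = TRUE)
  expect_equal(sum(confusion_counts(truth, pred)), 500L)

  expect_error(confusion_counts(c(1, 0), c(1, 0, 1)), "equal length")
  expect_error(confusion_counts(c(1, 2), c(1, 0)), "0/1")
})

test_that("every statistic equals an independent transcription of its formula", {
  set.seed(17)
  mine <- vector("list", 1000)
  oracle <- vector("list", 1000)
  for (case in 1:1000) {
    cc <- sample(0:40, 4, replace = TRUE)
    if (sum(cc) == 0) cc[1] <- 1
    mine[[case]] <- as.data.frame(
      classification_metrics(c(TP = cc[1], FP = cc[2], TN = cc[3], FN = cc[4])))
    oracle[[case]] <- as.data.frame(metrics_transcription(cc[1], cc[2], cc[3], cc[4]))
  }
  expect_equal(do.call(rbind, mine), do.call(rbind, oracle),
               ignore_attr = TRUE)
})

test_that("chance, perfect, and inverted classifiers hit the exact boundary values", {
  chance <- classification_metrics(c(TP = 50, FP = 50, TN = 50, FN = 50))
  expect_equal(chance$sensitivity, 0.5)
  expect_equal(chance$specificity, 0.5)
  expect_equal(chance$balanced_accuracy, 0.5)
  expect_equal(chance$mcc, 0)
  expect_equal(chance$youden, 0)
  expect_equal(chance$kappa, 0)

  perfect <- classification_metrics(c(TP = 30, FP = 0, TN = 70, FN = 0))
  expect_equal(perfect$mcc, 1)
  expect_equal(perfect$kappa, 1)
  expect_equal(perfect$youden, 1)
  expect_equal(perfect$f1, 1)

  inverted <- classification_metrics(c(TP = 0, FP = 70, TN = 0, FN = 30))
  expect_equal(inverted$mcc, -1)
  expect_equal(inverted$youden, -1)
})

test_that("MCC is symmetric under the simultaneous swap TP<->TN, FP<->FN", {
  set.seed(4)
  for (case in 1:50) {
    cc <- sample(1:30, 4, replace = TRUE)
    a <- classification_metrics(c(TP = cc[1], FP = cc[2], TN = cc[3], FN = cc[4]))$mcc
    b <- classification_metrics(c(TP = cc[3], FP = cc[4], TN = cc[1], FN = cc[2]))$mcc
    expect_equal(a, b)
  }
})

test_that("F1 is the harmonic mean of precision and recall where defined", {
  set.seed(8)
  for (case in 1:50) {
    cc <- sample(1:30, 4, replace = TRUE)
    r <- classification_metrics(c(TP = cc[1], FP = cc[2], TN = cc[3], FN = cc[4]))
    expect_equal(r$f1, 2 / (1 / r$precision + 1 / r$sensitivity))
  }
})

test_that("zero-denominator statistics are flagged undefined, not zeroed", {
  no_pred_pos <- classification_metrics(c(TP = 0, FP = 0, TN = 80, FN = 20))
  expect_true(is.na(no_pred_pos$precision))
  expect_true(is.na(no_pred_pos$mcc))
  expect_true(is.na(no_pred_pos$f1))
  expect_equal(no_pred_pos$specificity, 1)

  agg <- aggregate_metrics(rbind(
    as.data.frame(no_pred_pos),
    as.data.frame(classification_metrics(c(TP = 10, FP = 5, TN = 75, FN = 10)))))
  expect_equal(agg$n_undefined[agg$metric == "precision"], 1L)
  expect_equal(agg$n_used[agg$metric == "precision"], 1L)
  expect_equal(agg$mean[agg$metric == "precision"], 10 / 15)
})

test_that("balanced statistics recompute published comparator rows at printed precision", {
  pub <- published_comparison()
  bs <- balanced_stats(pub$sensitivity, pub$specificity)
  expect_equal(round(bs$balanced_accuracy, 3), pub$balanced_accuracy)
  expect_equal(round(bs$youden, 2), pub$youden)
  # spot value: Sn 0.674, Sp 0.849 -> BACC 0.7615, YI 0.523
  one <- balanced_stats(0.674, 0.849)
  expect_equal(one$balanced_accuracy, 0.7615)
  expect_equal(one$youden, 0.523)
})

test_that("decibel reconstruction error matches its definition and flags identity", {
  expect_equal(mse_db(matrix(0, 3, 3), matrix(0.01, 3, 3)), 40)
  m <- matrix(rnorm(20), 4, 5)
  expect_identical(mse_db(m, m), Inf)
  set.seed(12)
  a <- matrix(runif(60), 6, 10); b <- matrix(runif(60), 6, 10)
  direct <- -10 * log10(sum((a - b)^2) / 60)  # elementwise loop-free oracle
  expect_equal(mse_db(a, b), direct)
  expect_error(mse_db(a, matrix(0, 2, 2)), "shape")
})

test_that("ROC and PR areas behave on separable, chance, and degenerate scores", {
  truth <- c(rep(1, 20), rep(0, 80))
  sep <- c(runif(20, 0.8, 1), runif(80, 0, 0.2))
  expect_equal(roc_auc(sep, truth), 1)
  expect_equal(pr_auc(sep, truth), 1)

  set.seed(6)
  rnd <- runif(100)
  expect_lt(abs(roc_auc(rnd, truth) - 0.5), 0.2)
  # PR baseline for chance scores is about the positive prevalence
  expect_lt(abs(pr_auc(rnd, truth) - 0.2), 0.15)
  expect_true(is.na(roc_auc(rnd, rep(1, 100))))
})
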