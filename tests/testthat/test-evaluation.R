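test_that("confusion metrics match direct evaluation of the formulas", {
  m <- confusionMetrics(c(TP = 8, FN = 2, TN = 25, FP = 5))
  expect_equal(m$SE, 0.800)
  expect_equal(m$SP, 25 / 30, tolerance = 1e-12)
  expect_equal(m$Q, 0.825)
  expect_equal(m$MCC, 190 / sqrt(105300), tolerance = 1e-12)
  expect_equal(round(m$MCC, 4), 0.5855)
})

test_that("perfect and degenerate confusion matrices behave as defined", {
  p <- confusionMetrics(c(TP = 10, FN = 0, TN = 30, FP = 0))
  expect_equal(c(p$SE, p$SP, p$Q, p$MCC), c(1, 1, 1, 1))
  # everything predicted positive on an all-positive truth mix
  d <- confusionMetrics(c(TP = 10, FN = 0, TN = 0, FP = 0))
  expect_equal(d$MCC, 0)
  expect_true("MCC" %in% d$flagged)
  expect_error(confusionMetrics(c(TP = 0, FN = 0, TN = 0, FP = 0)), "zero")
})

test_that("MCC flips sign under prediction inversion; Q is symmetric", {
  set.seed(19)
  for (k in 1:25) {
    truth <- sample(c(1L, -1L), 30, replace = TRUE)
    pred <- sample(c(1L, -1L), 30, replace = TRUE)
    if (length(unique(truth)) < 2) next
    m <- confusionMetrics(countsFromPredictions(truth, pred))
    mInv <- confusionMetrics(countsFromPredictions(truth, -pred))
    expect_equal(mInv$MCC, -m$MCC, tolerance = 1e-12)
    cnt <- countsFromPredictions(truth, pred)
    swapped <- confusionMetrics(c(TP = cnt[["TN"]], FN = cnt[["FP"]],
                                  TN = cnt[["TP"]], FP = cnt[["FN"]]))
    expect_equal(swapped$Q, m$Q, tolerance = 1e-12)
  }
})

test_that("AUC matches brute-force pair counting", {
  expect_equal(computeAUC(c(0.9, 0.4, 0.5, 0.1), c(1, 1, -1, -1)), 0.75)
  expect_equal(computeAUC(c(5, 4, 2, 1), c(1, 1, -1, -1)), 1.0)
  expect_equal(computeAUC(rep(1, 10), rep(c(1, -1), 5)), 0.5)
  expect_error(computeAUC(1:4, rep(1, 4)), "both classes")
})

test_that("pair counting equals the trapezoidal ROC on random score sets", {
  set.seed(23)
  for (k in 1:200) {
    n <- sample(6:40, 1)
    labels <- c(1, -1, sample(c(1, -1), n - 2, replace = TRUE))
    scores <- round(stats::rnorm(n), sample(0:2, 1))  # force some ties
    expect_equal(computeAUC(scores, labels), aucTrapezoid(scores, labels),
                 tolerance = 1e-12)
  }
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(29)
  for (k in 1:20) {
    labels <- c(1, -1, sample(c(1, -1), 28, replace = TRUE))
    scores <- stats::rnorm(30) + (labels == 1)
    ref <- as.numeric(pROC::auc(pROC::roc(response = labels,
                                          predictor = scores,
                                          levels = c(-1, 1),
                                          direction = "<", quiet = TRUE)))
    expect_equal(computeAUC(scores, labels), ref, tolerance = 1e-10)
  }
})

test_that("stratified CV partitions each class into near-equal folds", {
  set.seed(37)
  n <- 100
  labels <- rep(c(1, -1), c(25, 75))
  # proxy feature 0 marks actives; features 2-4 are constant (base rate in
  # every fold), so separability is preserved in each training subset
  sets <- lapply(seq_len(n), function(i)
    sort(c(if (labels[i] == 1) 0L else integer(0), 2L, 3L, 4L)))
  fps <- fpSet(sets, nbits = 64L)
  cv <- kFoldCV(fps, labels, trainNaiveBayes, k = 5, seed = 101)
  expect_equal(sort(unique(cv$folds)), 1:5)
  expect_true(all(table(cv$folds) == 20))                 # 100 / 5
  expect_true(all(table(cv$folds[labels == 1]) == 5))     # stratified
  cv2 <- kFoldCV(fps, labels, trainNaiveBayes, k = 5, seed = 101)
  expect_identical(cv$folds, cv2$folds)                   # seed-reproducible
  expect_identical(cv$scores, cv2$scores)
  # pooled metrics equal metrics of the concatenated out-of-fold predictions
  pred <- ifelse(cv$scores > 0, 1L, -1L)
  expect_equal(cv$pooled$counts,
               confusionMetrics(countsFromPredictions(labels, pred))$counts)
  expect_equal(cv$pooled$AUC, computeAUC(cv$scores, labels))
  # the planted proxy feature separates every fold
  expect_equal(cv$pooled$AUC, 1.0)
})

test_that("CV rejects classes too small to stratify", {
  fps <- fpSet(list(0L, 1L, 2L, 3L, 4L, 5L), nbits = 8L)
  expect_error(kFoldCV(fps, c(1, 1, -1, -1, -1, -1), trainNaiveBayes, k = 5,
                       seed = 1), "stratify")
})

test_that("metric aggregation gives quartiles, mean and strict counts", {
  agg <- aggregateMetricTable(c(0.1, 0.2, 0.3), cutoff = 0.15)
  expect_equal(agg$countAbove, 2L)
  expect_equal(agg$Q2, 0.2)
  one <- aggregateMetricTable(0.42)
  expect_equal(c(one$minimum, one$Q2, one$maximum, one$mean), rep(0.42, 4))
  expect_error(aggregateMetricTable(numeric(0)), "empty")
  # inclusive linear interpolation, and ordering invariant
  v <- c(0.9, 0.1, 0.5, 0.3)
  agg2 <- aggregateMetricTable(v)
  expect_equal(agg2$Q1, unname(quantile(v, 0.25, type = 7)))
  expect_true(agg2$minimum <= agg2$Q1 && agg2$Q1 <= agg2$Q2 &&
              agg2$Q2 <= agg2$Q3 && agg2$Q3 <= agg2$maximum)
  # strict inequality at the cutoff
  expect_equal(aggregateMetricTable(c(0.8, 0.81), cutoff = 0.8)$countAbove, 1L)
})

test_that("bundled benchmark tables load in wide and long form", {
  cv <- benchmarkTable("cv")
  te <- benchmarkTable("test")
  expect_equal(nrow(cv), 26L)
  expect_equal(nrow(te), 26L)
  long <- benchmarkLong(te)
  expect_equal(nrow(long), 104L)
  expect_setequal(unique(long$algorithm), c("nb", "rp"))
  expect_equal(sum(long$gene == "IDE"), 4L)
})
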