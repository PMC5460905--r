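# Laplacian-corrected naive Bayes -------------------------------------------

test_that("NB weights follow the Laplacian-corrected formula", {
  # 4 compounds, 1 active => P(+) = 0.25
  fps <- fpSet(list(c(0, 1), 0, 2, 3))
  m <- trainNaiveBayes(fps, c(1, -1, -1, -1))
  expect_equal(m@prior, 0.25)
  # feature 0 in 2 compounds, 1 active: ln(2 / 1.5)
  expect_equal(unname(m@weights["0"]), log(2 / 1.5), tolerance = 1e-12)
  # a feature at exactly the base rate has weight 0
  fps2 <- fpSet(list(0, 0, 0, 0))
  m2 <- trainNaiveBayes(fps2, c(1, -1, -1, -1))
  expect_equal(unname(m2@weights["0"]), 0, tolerance = 1e-12)
  # feature in 4 compounds, none active, P(+) = 0.25: ln(1 / 2)
  fps3 <- fpSet(list(1, 1, 0, 0, 0, 0, 2, 3))
  m3 <- trainNaiveBayes(fps3, c(1, 1, -1, -1, -1, -1, -1, -1))
  expect_equal(unname(m3@weights["0"]), log(1 / 2), tolerance = 1e-12)
})

test_that("NB scores sum feature weights; unseen features contribute zero", {
  fps <- fpSet(list(c(0, 1), 0, 2, 3))
  m <- trainNaiveBayes(fps, c(1, -1, -1, -1))
  w0 <- unname(m@weights["0"]); w1 <- unname(m@weights["1"])
  probe <- fpSet(list(c(0, 1), integer(0), c(0, 1, 9, 10)))
  s <- modelScores(m, probe)
  expect_equal(s[1], w0 + w1)
  expect_equal(s[2], 0)            # empty fingerprint scores 0
  expect_equal(s[3], w0 + w1)      # 9, 10 unseen in training
})

test_that("NB training rejects degenerate inputs", {
  fps <- fpSet(list(0, 1))
  expect_error(trainNaiveBayes(fps, c(1, 1)), "both classes")
  expect_error(trainNaiveBayes(fpSet(list()), integer(0)), "empty")
  m <- trainNaiveBayes(fpSet(list(0, 1)), c(1, -1))
  expect_error(modelScores(m, fpSet(list(0), scheme = "MACCS166",
                                    nbits = 166L)), "mismatch")
})

test_that("NB score is additive over feature-set unions", {
  set.seed(77)
  sets <- randomFeatureSets(40, nbits = 32L)
  labels <- rep(c(1, -1), 20)
  m <- trainNaiveBayes(fpSet(sets, nbits = 32L), labels)
  for (k in 1:20) {
    ab <- sets[sample(40, 2)]
    u <- sort(union(ab[[1]], ab[[2]])); i <- sort(intersect(ab[[1]], ab[[2]]))
    s <- modelScores(m, fpSet(list(ab[[1]], ab[[2]], u, i), nbits = 32L))
    expect_equal(s[3], s[1] + s[2] - s[4], tolerance = 1e-10)
  }
})

test_that("a perfect proxy feature yields training AUC 1", {
  set.seed(5)
  n <- 40
  labels <- rep(c(1, -1), each = n / 2)
  # class-balanced noise features sit at the base rate (weight 0), so the
  # proxy alone determines the ranking
  sets <- lapply(seq_len(n), function(i)
    if (labels[i] == 1) c(0L, 10L, 11L) else c(10L, 11L))
  extra <- lapply(12:20, function(f) {
    k <- sample(3:8, 1)
    c(sample(which(labels == 1), k), sample(which(labels == -1), k))
  })
  for (j in seq_along(extra)) for (i in extra[[j]])
    sets[[i]] <- sort(unique(c(sets[[i]], 11L + j)))
  fps <- fpSet(sets, nbits = 32L)
  m <- trainNaiveBayes(fps, labels)
  balanced <- as.character(12:20)
  expect_true(all(abs(m@weights[balanced[balanced %in% names(m@weights)]])
                  < 1e-12))
  expect_equal(computeAUC(modelScores(m, fps), labels), 1.0)
})

test_that("topFeatures ranks by weight with index tie-breaks", {
  fps <- fpSet(list(c(0, 1), 0, 2, 3))
  m <- trainNaiveBayes(fps, c(1, -1, -1, -1))
  best <- topFeatures(m, 1)
  expect_equal(best$feature, 1L)   # only-in-active feature wins
  all4 <- topFeatures(m, 99)
  expect_equal(nrow(all4), 4L)     # k beyond feature count returns all
  expect_error(topFeatures(m, 0), "positive")
  # all-equal weights fall back to ascending index order
  mEq <- trainNaiveBayes(fpSet(list(c(0, 5, 9), c(0, 5, 9))), c(1, -1))
  expect_equal(topFeatures(mEq, 3)$feature, c(0L, 5L, 9L))
})

test_that("threshold calibration picks an MCC-optimal cutoff", {
  set.seed(9)
  labels <- rep(c(1, -1), each = 20)
  sets <- lapply(seq_along(labels), function(i)
    sort(unique(c(if (labels[i] == 1) c(0L, 1L) else integer(0),
                  sample(5:20, 3)))))
  fps <- fpSet(sets, nbits = 32L)
  m <- calibrateThreshold(trainNaiveBayes(fps, labels), fps, labels)
  pred <- modelPredict(m, fps)
  expect_equal(confusionMetrics(countsFromPredictions(labels, pred))$MCC, 1.0)
})

# Recursive partitioning -----------------------------------------------------

test_that("a perfectly separating feature yields a depth-1 pure tree", {
  labels <- rep(c(1, -1), each = 4)
  sets <- lapply(seq_along(labels), function(i)
    if (labels[i] == 1) c(0L, 3L) else 3L)
  fps <- fpSet(sets)
  m <- trainRecursivePartitioning(fps, labels, maxDepth = 5,
                                  minSamplesPerNode = 1)
  expect_equal(nrow(m@tree), 3L)            # root + two leaves
  expect_equal(m@tree$feature[1], 0L)
  expect_equal(unname(modelPredict(m, fps)), labels)
  # children of a pure split stay leaves regardless of depth budget
  expect_true(all(m@tree$leaf[-1]))
})

test_that("XOR labels over two features resolve at depth 2", {
  fps <- fpSet(list(integer(0), 0L, 1L, c(0L, 1L)))
  labels <- c(-1, 1, 1, -1)
  m <- trainRecursivePartitioning(fps, labels, maxDepth = 2,
                                  minSamplesPerNode = 1)
  expect_equal(unname(modelPredict(m, fps)), labels)
})

test_that("RP training accuracy is non-decreasing in maxDepth", {
  set.seed(31)
  n <- 60
  labels <- rep(c(1, -1), each = n / 2)
  sets <- lapply(seq_len(n), function(i) {
    base <- if (labels[i] == 1) sample(0:3, 2) else sample(2:6, 2)
    sort(unique(c(base, sample(8:24, 3))))
  })
  fps <- fpSet(sets, nbits = 32L)
  prev <- 0
  for (d in c(1, 2, 4, 8)) {
    m <- trainRecursivePartitioning(fps, labels, maxDepth = d,
                                    minSamplesPerNode = 1)
    acc <- mean(modelPredict(m, fps) == labels)
    expect_gte(acc, prev)
    prev <- acc
  }
})

test_that("RP predictions report leaf class proportions deterministically", {
  # force a 3-active/1-decoy leaf: feature 0 splits, impure child remains
  fps <- fpSet(list(0L, 0L, 0L, 0L, 1L, 1L, 1L, 1L))
  labels <- c(1, 1, 1, -1, -1, -1, -1, -1)
  m <- trainRecursivePartitioning(fps, labels, maxDepth = 1,
                                  minSamplesPerNode = 4)
  pr <- predictRP(m, fpSet(list(0L, integer(0))))
  expect_equal(pr$activeFraction, c(0.75, 0))
  expect_equal(pr$label, c(1L, -1L))
  expect_identical(predictRP(m, fps), predictRP(m, fps))
})

test_that("RP rejects invalid parameters and single-class data", {
  fps <- fpSet(list(0L, 1L))
  expect_error(trainRecursivePartitioning(fps, c(1, 1)), "both classes")
  expect_error(trainRecursivePartitioning(fps, c(1, -1), maxDepth = 0),
               "maxDepth")
})

# Serialization ---------------------------------------------------------------

test_that("models round-trip through JSON with identical scores", {
  set.seed(13)
  labels <- rep(c(1, -1), each = 15)
  sets <- lapply(seq_along(labels), function(i)
    sort(unique(c(if (labels[i] == 1) 0L else integer(0), sample(2:30, 5)))))
  fps <- fpSet(sets, nbits = 64L)
  probes <- fpSet(randomFeatureSets(100, nbits = 64L), nbits = 64L)

  nb <- trainNaiveBayes(fps, labels)
  rp <- trainRecursivePartitioning(fps, labels, minSamplesPerNode = 2)
  for (m in list(nb, rp)) {
    path <- withr::local_tempfile(fileext = ".json")
    saveModel(m, path)
    back <- loadModel(path)
    expect_identical(modelScores(back, probes), modelScores(m, probes))
    expect_identical(modelPredict(back, probes), modelPredict(m, probes))
  }
})

test_that("corrupted or mis-versioned model files are rejected", {
  fps <- fpSet(list(c(0, 1), 0, 2, 3))
  m <- trainNaiveBayes(fps, c(1, -1, -1, -1))
  path <- withr::local_tempfile(fileext = ".json")
  saveModel(m, path)
  txt <- readLines(path)
  writeLines(substr(paste(txt, collapse = ""), 1, 40), path)  # truncate
  expect_error(loadModel(path))
  jsonlite::write_json(list(format_version = 99, algorithm = "nb"), path,
                       auto_unbox = TRUE)
  expect_error(loadModel(path), "version")
})
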