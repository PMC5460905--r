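makePool <- function(n, prefix = "p") {
  # simple valid alkane/ether chains, structurally distinct
  smis <- vapply(seq_len(n), function(i)
    paste0(strrep("C", (i %% 7) + 1), if (i %% 2) "O" else "",
           strrep("C", (i %% 5) + 1)), character(1))
  CompoundSet(sprintf("%s%03d", prefix, seq_len(n)), smis)
}

test_that("decoy sampling honors the ratio and excludes active structures", {
  actives <- CompoundSet(paste0("a", 1:10),
                         paste0("c1ccccc1", strrep("C", 1:10)), label = 1L)
  pool <- makePool(100)
  d <- sampleDecoys(actives, pool, ratio = 3, seed = 5)
  expect_length(d, 30L)
  expect_true(all(compoundLabels(d) == -1L))
  expect_length(intersect(canonicalSmiles(compoundSmiles(d)),
                          canonicalSmiles(compoundSmiles(actives))), 0L)
  d2 <- sampleDecoys(actives, pool, ratio = 3, seed = 5)
  expect_identical(compoundIds(d2), compoundIds(d))   # seed-reproducible
})

test_that("pool copies of an active are excluded before sampling", {
  actives <- CompoundSet("a1", "CCO", label = 1L)
  pool <- CompoundSet(paste0("p", 1:8),
                      c("OCC", "C(O)C", "CCO", "CCC", "CCCC", "CCCCC",
                        "CCN", "CCCN"))
  d <- sampleDecoys(actives, pool, ratio = 3, seed = 1)
  expect_false(canonicalSmiles("CCO") %in% canonicalSmiles(compoundSmiles(d)))
})

test_that("an undersized pool fails with the shortfall", {
  actives <- CompoundSet(paste0("a", 1:10), paste0("CCO", strrep("C", 1:10)),
                         label = 1L)
  expect_error(sampleDecoys(actives, makePool(20), ratio = 3, seed = 1),
               "short")
})

test_that("property-matched sampling tracks the actives' weight range", {
  set.seed(61)
  actives <- CompoundSet(paste0("a", 1:12),
                         paste0("c1ccccc1", strrep("C", 3:14)), label = 1L)
  pool <- makePool(200)
  d <- sampleDecoys(actives, pool, ratio = 3, seed = 11,
                    propertyMatched = TRUE)
  expect_length(d, 36L)
})

test_that("train/test split is stratified 3:1 with train-side rounding", {
  actives <- CompoundSet(paste0("a", 1:8), paste0("CCO", strrep("C", 1:8)),
                         label = 1L)
  pool <- makePool(100)
  decoys <- sampleDecoys(actives, pool, ratio = 3, seed = 3)
  ms <- ModelingSet(list(gene_symbol = "T1"), actives, decoys)
  ms <- splitTrainTest(ms, ratio = 3, seed = 7)
  sp <- msSplit(ms)
  expect_equal(sum(sp[compoundIds(actives)] == "train"), 6L)
  expect_equal(sum(sp[compoundIds(actives)] == "test"), 2L)
  expect_equal(sum(sp[compoundIds(decoys)] == "train"), 18L)
  expect_equal(sum(sp[compoundIds(decoys)] == "test"), 6L)
  ms2 <- splitTrainTest(ms, ratio = 3, seed = 7)
  expect_identical(msSplit(ms2), sp)
  # ratio 1 halves each class
  msHalf <- splitTrainTest(ms, ratio = 1, seed = 7)
  expect_equal(sum(msSplit(msHalf)[compoundIds(actives)] == "train"), 4L)
})

test_that("classes below ratio+1 members cannot be split", {
  a <- CompoundSet(paste0("a", 1:3), c("CCO", "CCN", "CCC"), label = 1L)
  d <- CompoundSet(paste0("d", 1:9), paste0("CCOC", strrep("C", 1:9)),
                   label = -1L)
  ms <- ModelingSet(list(gene_symbol = "T1"), a, d)
  expect_error(splitTrainTest(ms, ratio = 3, seed = 1), "ratio\\+1")
})

test_that("generator parameters are validated", {
  expect_error(makeSyntheticBenchmark(signalStrength = 0), "signalStrength")
  expect_error(makeSyntheticBenchmark(signalStrength = 1.2), "signalStrength")
  expect_error(makeSyntheticBenchmark(nActivesPerTarget = 10), "20")
  expect_error(makeSyntheticBenchmark(nTargets = 99), "between")
})

test_that("generated SMILES are chemically valid and seed-stable", {
  b1 <- makeSyntheticBenchmark(nTargets = 2, nActivesPerTarget = 20,
                               seed = 303)
  b2 <- makeSyntheticBenchmark(nTargets = 2, nActivesPerTarget = 20,
                               seed = 303)
  for (g in names(b1$sets)) {
    expect_identical(compoundSmiles(msActives(b1$sets[[g]])),
                     compoundSmiles(msActives(b2$sets[[g]])))
    expect_identical(compoundSmiles(msDecoys(b1$sets[[g]])),
                     compoundSmiles(msDecoys(b2$sets[[g]])))
  }
  smis <- unlist(lapply(b1$sets, function(ms)
    c(compoundSmiles(msActives(ms)), compoundSmiles(msDecoys(ms)))))
  expect_false(any(is.na(canonicalSmiles(smis))))
  # different seeds produce different sets
  b3 <- makeSyntheticBenchmark(nTargets = 2, nActivesPerTarget = 20,
                               seed = 304)
  expect_false(identical(compoundSmiles(msActives(b1$sets[[1]])),
                         compoundSmiles(msActives(b3$sets[[1]]))))
})

test_that("at full signal every active carries its scaffold", {
  b <- makeSyntheticBenchmark(nTargets = 1, nActivesPerTarget = 20,
                              signalStrength = 1, seed = 71)
  expect_true(all(b$activeDetails$carries_scaffold))
  # NB ranks a held-out scaffold-bearing compound above a scaffold-free one
  ms <- b$sets[[1]]
  train <- msCompounds(ms, "train")
  fps <- computeFingerprints(train, "ECFP6")
  m <- trainNaiveBayes(fps, train@label)
  scaf <- b$truth$scaffold[1]
  probe <- computeFingerprints(
    c(withScaf = paste0("CC", scaf, "CC"), without = "CCCCOCC"), "ECFP6")
  s <- modelScores(m, probe)
  expect_gt(s[1], s[2])
})

test_that("the standard benchmark recovers the planted scaffold", {
  bench <- standardBenchmark()
  ms <- bench$sets[[1]]
  expect_length(msActives(ms), 100L)
  expect_length(msDecoys(ms), 300L)
  q <- standardQuartet()
  top1 <- topFeatures(q$nb_ecfp6, 1)$feature
  det <- bench$activeDetails
  carrier <- det[det$carries_scaffold, ][1, ]
  smi <- compoundSmiles(msActives(ms))[[carrier$compound_id]]
  env <- ecfpEnvironments(smi, "ECFP6")
  hit <- env[env$feature == top1, ]
  expect_gt(nrow(hit), 0)
  scafAtoms <- carrier$scaffold_offset + seq_len(carrier$scaffold_length)
  # the top feature's defining environment sits inside the planted scaffold
  expect_true(any(hit$center %in% scafAtoms))
  expect_true(all(hit$atoms[[1]] %in% scafAtoms) ||
              any(hit$center %in% scafAtoms))
})

test_that("modeling sets persist as plain-text directories", {
  b <- makeSyntheticBenchmark(nTargets = 1, nActivesPerTarget = 20,
                              seed = 99)
  ms <- b$sets[[1]]
  dir <- withr::local_tempdir()
  writeModelingSet(ms, dir)
  expect_true(all(file.exists(file.path(dir, c("actives.smi", "decoys.smi",
                                               "split.csv",
                                               "manifest.json")))))
  back <- readModelingSet(dir)
  expect_identical(compoundSmiles(msActives(back)),
                   compoundSmiles(msActives(ms)))
  expect_identical(msSplit(back), msSplit(ms))
  expect_equal(msTarget(back)$gene_symbol, msTarget(ms)$gene_symbol)
})

test_that("target tables enforce the seven-class mechanism vocabulary", {
  expect_length(mechanismClasses, 7L)
  good <- data.frame(gene_symbol = c("AA", "BB"),
                     subfamily = c("neurotransmission",
                                   "tau_pathology;abeta_related"))
  expect_silent(validateTargetTable(good))
  dup <- data.frame(gene_symbol = c("AA", "AA"),
                    subfamily = rep("neurotransmission", 2))
  expect_error(validateTargetTable(dup), "unique")
  bad <- data.frame(gene_symbol = "AA", subfamily = "telepathy")
  expect_error(validateTargetTable(bad), "telepathy")
})
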