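# Classification quality: confusion metrics, ROC AUC, stratified k-fold
# cross-validation, and summary aggregation across model libraries.

#' Confusion counts from true and predicted labels
#'
#' @param truth,pred integer vectors of `+1`/`-1` labels.
#' @return named integer vector with `TP`, `FN`, `TN`, `FP`.
#' @export
countsFromPredictions <- function(truth, pred) {
  stopifnot(length(truth) == length(pred))
  c(TP = sum(truth == 1L & pred == 1L),
    FN = sum(truth == 1L & pred == -1L),
    TN = sum(truth == -1L & pred == -1L),
    FP = sum(truth == -1L & pred == 1L))
}

#' Confusion-matrix classification metrics
#'
#' Computes sensitivity `SE = TP/(TP+FN)`, specificity `SP = TN/(TN+FP)`,
#' overall accuracy `Q = (TP+TN)/(TP+TN+FP+FN)` and the Matthews correlation
#' coefficient
#' \deqn{MCC = \frac{TP \cdot TN - FN \cdot FP}
#'   {\sqrt{(TP+FN)(TP+FP)(TN+FN)(TN+FP)}}.}
#' Any metric whose denominator is zero is reported as 0 and listed in the
#' `flagged` component.
#'
#' @param counts named vector/list with `TP`, `FN`, `TN`, `FP` (see
#'   [countsFromPredictions()]).
#' @return list with `counts`, `SE`, `SP`, `Q`, `MCC` and `flagged`.
#' @examples
#' m <- confusionMetrics(c(TP = 8, FN = 2, TN = 25, FP = 5))
#' round(c(m$SE, m$SP, m$Q, m$MCC), 4)
#' @export
confusionMetrics <- function(counts) {
  TP <- as.numeric(counts[["TP"]]); FN <- as.numeric(counts[["FN"]])
  TN <- as.numeric(counts[["TN"]]); FP <- as.numeric(counts[["FP"]])
  if (any(c(TP, FN, TN, FP) < 0)) stop("confusion counts must be non-negative")
  total <- TP + FN + TN + FP
  if (total == 0) stop("confusion counts are all zero")
  flagged <- character(0)
  safe <- function(num, den, what) {
    if (den == 0) { flagged <<- c(flagged, what); 0 } else num / den
  }
  SE <- safe(TP, TP + FN, "SE")
  SP <- safe(TN, TN + FP, "SP")
  Q  <- (TP + TN) / total
  mccDen <- (TP + FN) * (TP + FP) * (TN + FN) * (TN + FP)
  MCC <- safe(TP * TN - FN * FP, sqrt(mccDen), "MCC")
  list(counts = c(TP = TP, FN = FN, TN = TN, FP = FP),
       SE = SE, SP = SP, Q = Q, MCC = MCC, flagged = flagged)
}

#' ROC AUC by pair counting (Mann-Whitney statistic)
#'
#' The fraction of (active, decoy) pairs in which the active scores strictly
#' higher, ties counted 1/2 — identical to the trapezoidal area under the
#' threshold-swept ROC curve (see [aucTrapezoid()], maintained as the
#' independent cross-check).
#'
#' @param scores numeric classifier scores.
#' @param labels integer `+1`/`-1` truth labels.
#' @return AUC in `[0, 1]`.
#' @examples
#' computeAUC(c(0.9, 0.4, 0.5, 0.1), c(1, 1, -1, -1))  # 0.75
#' @export
computeAUC <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L); n0 <- sum(labels == -1L)
  if (n1 == 0 || n0 == 0) stop("AUC requires both classes")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC AUC by explicit threshold sweep (trapezoidal rule)
#'
#' Direct construction of the ROC curve by iterating over every distinct
#' score as a classification threshold, integrated with the trapezoidal rule.
#'
#' @inheritParams computeAUC
#' @return AUC in `[0, 1]`.
#' @export
aucTrapezoid <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L); n0 <- sum(labels == -1L)
  if (n1 == 0 || n0 == 0) stop("AUC requires both classes")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  tpr <- c(0); fpr <- c(0)
  i <- 1L; tp <- 0; fp <- 0
  n <- length(s)
  while (i <= n) {
    j <- i
    while (j < n && s[j + 1] == s[i]) j <- j + 1L
    tp <- tp + sum(y[i:j] == 1L)
    fp <- fp + sum(y[i:j] == -1L)
    tpr <- c(tpr, tp / n1); fpr <- c(fpr, fp / n0)
    i <- j + 1L
  }
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}

metricsFromScores <- function(truth, pred, scores) {
  m <- confusionMetrics(countsFromPredictions(truth, pred))
  m$AUC <- computeAUC(scores, truth)
  m
}

#' Stratified k-fold cross-validation
#'
#' Splits compounds into `k` stratified folds (per-class fold sizes differing
#' by at most one), trains on each k-1 fold union and scores the held-out
#' fold, so every compound is validated exactly once. Metrics are pooled over
#' the concatenated out-of-fold predictions (not averaged across folds).
#' Fully reproducible from `seed`.
#'
#' @param fps a [FingerprintSet-class] for the full data set.
#' @param labels integer `+1`/`-1` labels.
#' @param trainer function `(fps, labels) -> model`, e.g.
#'   `trainNaiveBayes` or `trainRecursivePartitioning` (possibly with
#'   parameters fixed via an anonymous function).
#' @param k number of folds (default 5).
#' @param seed integer seed for fold assignment.
#' @return list with `pooled` (metrics of concatenated predictions, incl.
#'   AUC), `perFold` (list of per-fold metric lists), `folds` (assignment)
#'   and `scores` (out-of-fold scores in input order).
#' @export
kFoldCV <- function(fps, labels, trainer, k = 5L, seed = 2017L) {
  stopifnot(is(fps, "FingerprintSet"))
  n <- length(fps@features)
  labels <- checkLabels(labels, n)
  if (k < 2) stop("k must be >= 2")
  perClassMin <- min(table(labels))
  if (perClassMin < k)
    stop("smallest class (", perClassMin, ") too small to stratify into ",
         k, " folds")
  folds <- integer(n)
  withSeed(seed, {
    for (cls in c(1L, -1L)) {
      idx <- which(labels == cls)
      folds[idx] <- (sample(seq_along(idx)) %% k) + 1L
    }
  })
  scores <- numeric(n)
  preds <- integer(n)
  perFold <- vector("list", k)
  for (f in seq_len(k)) {
    test <- which(folds == f)
    train <- which(folds != f)
    model <- trainer(fps[train], labels[train])
    scores[test] <- modelScores(model, fps[test])
    preds[test] <- modelPredict(model, fps[test])
    perFold[[f]] <- metricsFromScores(labels[test], preds[test], scores[test])
  }
  pooled <- metricsFromScores(labels, preds, scores)
  list(pooled = pooled, perFold = perFold, folds = folds, scores = scores)
}

#' Summary statistics and threshold counts for a metric collection
#'
#' Five-number summary (minimum, quartiles by inclusive linear interpolation,
#' maximum), mean, and optionally the count of values strictly greater than a
#' cutoff — the aggregation used to summarize large model libraries.
#'
#' @param values numeric metric values (e.g. per-model MCC or AUC).
#' @param cutoff optional threshold; when given, `countAbove` holds
#'   `sum(values > cutoff)` (strict).
#' @return list with `n`, `minimum`, `Q1`, `Q2`, `Q3`, `maximum`, `mean` and
#'   (if requested) `cutoff`, `countAbove`, `fracAbove`.
#' @examples
#' aggregateMetricTable(c(0.1, 0.2, 0.3), cutoff = 0.15)$countAbove  # 2
#' @export
aggregateMetricTable <- function(values, cutoff = NULL) {
  values <- as.numeric(values)
  if (!length(values)) stop("empty metric collection")
  q <- unname(stats::quantile(values, c(0.25, 0.5, 0.75), type = 7))
  out <- list(n = length(values), minimum = min(values), Q1 = q[1],
              Q2 = q[2], Q3 = q[3], maximum = max(values),
              mean = mean(values))
  if (!is.null(cutoff)) {
    out$cutoff <- cutoff
    out$countAbove <- sum(values > cutoff)
    out$fracAbove <- out$countAbove / out$n
  }
  out
}

#' Bundled multi-target AD classifier benchmark tables
#'
#' Published per-target performance of a 104-classifier library (26
#' preclinical Alzheimer's-disease targets x 2 fingerprints x 2 algorithms):
#' 5-fold cross-validation results (`"cv"`), external test-set results
#' (`"test"`), and the per-target data-set composition with mean pairwise
#' Tanimoto diversity (`"summary"`). Values are MCC and ROC AUC per
#' classifier variant.
#'
#' @param which `"cv"`, `"test"` or `"summary"`.
#' @return data.frame, one row per target gene symbol.
#' @examples
#' cv <- benchmarkTable("cv")
#' aggregateMetricTable(unlist(cv[grep("mcc", names(cv))]), cutoff = 0.8)
#' @export
benchmarkTable <- function(which = c("cv", "test", "summary")) {
  which <- match.arg(which)
  file <- switch(which, cv = "cv_performance.csv",
                 test = "test_performance.csv",
                 summary = "dataset_summary.csv")
  path <- system.file("extdata", file, package = "mtqsar", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Long-format view of a benchmark performance table
#'
#' @param df a table from [benchmarkTable()] (`"cv"` or `"test"`).
#' @return data.frame with columns `gene`, `algorithm` (`nb`/`rp`), `scheme`
#'   (`ecfp6`/`maccs`), `mcc`, `auc`.
#' @export
benchmarkLong <- function(df) {
  combos <- expand.grid(algorithm = c("nb", "rp"),
                        scheme = c("ecfp6", "maccs"),
                        stringsAsFactors = FALSE)
  out <- do.call(rbind, lapply(seq_len(nrow(combos)), function(i) {
    pre <- paste0(combos$algorithm[i], "_", combos$scheme[i])
    data.frame(gene = df$gene, algorithm = combos$algorithm[i],
               scheme = combos$scheme[i],
               mcc = df[[paste0(pre, "_mcc")]],
               auc = df[[paste0(pre, "_auc")]],
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Write a metrics table in the benchmark layout
#'
#' One row per (target, algorithm, scheme) with SE/SP/Q/MCC/AUC columns,
#' mirroring the per-target performance tables.
#'
#' @param rows data.frame with columns `target`, `algorithm`, `scheme`,
#'   `eval_kind` and metric columns.
#' @param path output CSV.
#' @return `path`, invisibly.
#' @export
writeMetricsTable <- function(rows, path) {
  num <- vapply(rows, is.numeric, logical(1))
  rows[num] <- lapply(rows[num], function(x) round(x, 6))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
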