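# The two classifier families: Laplacian-corrected naive Bayes and
# recursive-partitioning decision trees, both consuming binary fingerprints.

checkLabels <- function(labels, n) {
  labels <- as.integer(labels)
  if (length(labels) != n)
    stop("labels must be parallel to the fingerprint set")
  if (any(is.na(labels)) || !all(labels %in% c(1L, -1L)))
    stop("labels must be +1 (active) or -1 (decoy)")
  if (length(unique(labels)) < 2L)
    stop("training data must contain both classes")
  labels
}

#' Train a Laplacian-corrected naive Bayes classifier
#'
#' The standard fingerprint-Bayesian learner for ligand-based screening.
#' With prior active fraction `P = nActive / nTrain`, a feature `f` observed
#' in `T_f` training compounds of which `A_f` are active receives the
#' Laplacian-corrected log-weight
#' \deqn{W_f = \log\frac{A_f + 1}{T_f \, P + 1}}
#' i.e. the smoothed ratio of the feature's active rate to the base rate: a
#' feature occurring at exactly the base rate gets weight 0, enrichment among
#' actives gives positive weight, depletion negative. Unseen features score 0.
#'
#' @param fps a [FingerprintSet-class] of training compounds.
#' @param labels integer vector, `+1` active / `-1` decoy.
#' @param threshold decision cutoff on the additive score (default 0; see
#'   [calibrateThreshold()]).
#' @return an [NBModel-class].
#' @examples
#' fps <- new("FingerprintSet", scheme = "ECFP6", nbits = 8L,
#'            features = list(c(0L, 1L), 0L, 2L, 3L),
#'            ids = paste0("c", 1:4))
#' m <- trainNaiveBayes(fps, c(1, -1, -1, -1))
#' topFeatures(m, 2)
#' @export
trainNaiveBayes <- function(fps, labels, threshold = 0) {
  stopifnot(is(fps, "FingerprintSet"))
  n <- length(fps@features)
  if (n == 0) stop("empty training data")
  labels <- checkLabels(labels, n)
  prior <- sum(labels == 1L) / n
  allFeats <- unlist(fps@features, use.names = FALSE)
  featOf <- rep(labels, lengths(fps@features))
  Tf <- table(allFeats)
  Af <- table(allFeats[featOf == 1L])
  featNames <- names(Tf)
  a <- numeric(length(featNames))
  names(a) <- featNames
  a[names(Af)] <- as.numeric(Af)
  w <- log((a + 1) / (as.numeric(Tf) * prior + 1))
  names(w) <- featNames
  new("NBModel", prior = prior, weights = w, nTrain = as.integer(n),
      nActive = as.integer(sum(labels == 1L)), scheme = fps@scheme,
      nbits = fps@nbits, threshold = as.numeric(threshold))
}

checkSchemeMatch <- function(model, fps) {
  if (model@scheme != fps@scheme || model@nbits != fps@nbits)
    stop(sprintf("fingerprint scheme mismatch: model %s/%d vs input %s/%d",
                 model@scheme, model@nbits, fps@scheme, fps@nbits))
}

#' @rdname modelScores
#' @export
setMethod("modelScores", signature("NBModel", "FingerprintSet"),
  function(model, fps) {
    checkSchemeMatch(model, fps)
    vapply(fps@features, function(f) {
      if (!length(f)) return(0)
      w <- model@weights[as.character(f)]
      sum(w, na.rm = TRUE)   # features unseen in training contribute 0
    }, numeric(1))
  })

#' @rdname modelPredict
#' @export
setMethod("modelPredict", signature("NBModel", "FingerprintSet"),
  function(model, fps) {
    s <- modelScores(model, fps)
    ifelse(s > model@threshold, 1L, -1L)
  })

#' Top-weighted features of a naive Bayes model
#'
#' The `k` features with the largest log-weights, in descending order; ties
#' are broken by ascending feature index. These are the substructure
#' environments the model considers most activity-enriched.
#'
#' @param model a trained [NBModel-class].
#' @param k number of features to return (capped at the number observed).
#' @return data.frame with columns `feature` (index) and `weight`.
#' @export
topFeatures <- function(model, k) {
  stopifnot(is(model, "NBModel"))
  if (k <= 0) stop("k must be positive")
  idx <- as.integer(names(model@weights))
  ord <- order(-model@weights, idx)
  take <- ord[seq_len(min(k, length(ord)))]
  data.frame(feature = idx[take], weight = unname(model@weights[take]))
}

#' Calibrate the naive Bayes decision threshold
#'
#' Chooses the score cutoff maximizing the Matthews correlation coefficient
#' on the supplied (training) data; candidate cutoffs are midpoints between
#' adjacent distinct scores.
#'
#' @param model a trained [NBModel-class].
#' @param fps training [FingerprintSet-class].
#' @param labels training labels (`+1`/`-1`).
#' @return the model with an updated `threshold`.
#' @export
calibrateThreshold <- function(model, fps, labels) {
  labels <- checkLabels(labels, length(fps@features))
  s <- modelScores(model, fps)
  su <- sort(unique(s))
  cand <- if (length(su) > 1) (su[-1] + su[-length(su)]) / 2 else su
  cand <- c(min(su) - 1, cand)
  best <- model@threshold
  bestMCC <- -Inf
  for (th in cand) {
    pred <- ifelse(s > th, 1L, -1L)
    mcc <- confusionMetrics(countsFromPredictions(labels, pred))$MCC
    if (mcc > bestMCC + 1e-12) { bestMCC <- mcc; best <- th }
  }
  model@threshold <- best
  model
}

# ---- Recursive partitioning ------------------------------------------------

giniImpurity <- function(nAct, nTot) {
  if (nTot == 0) return(0)
  p <- nAct / nTot
  2 * p * (1 - p)
}

#' Train a recursive-partitioning decision tree
#'
#' Grows a binary classification tree by successive splits on the presence or
#' absence of single fingerprint features, chosen greedily by Gini impurity
#' decrease over all features observed in the node (exhaustive search, ties
#' broken by the smallest feature index). A node is split only if both
#' children would hold at least `minSamplesPerNode` compounds; splitting also
#' stops at pure nodes and at `maxDepth`. Zero-improvement splits are allowed
#' (so e.g. XOR-structured labels over two features are resolved at depth 2).
#' Leaves predict the majority class, ties going to the decoy class.
#'
#' @param fps a [FingerprintSet-class] of training compounds.
#' @param labels integer vector, `+1` active / `-1` decoy.
#' @param maxDepth maximum tree depth (root = depth 0); default 20.
#' @param minSamplesPerNode minimum compounds in any node; default 10.
#' @return an [RPModel-class].
#' @export
trainRecursivePartitioning <- function(fps, labels, maxDepth = 20L,
                                       minSamplesPerNode = 10L) {
  stopifnot(is(fps, "FingerprintSet"))
  n <- length(fps@features)
  if (n == 0) stop("empty training data")
  labels <- checkLabels(labels, n)
  if (maxDepth < 1) stop("maxDepth must be >= 1")
  if (minSamplesPerNode < 1) stop("minSamplesPerNode must be >= 1")
  observed <- sort(unique(unlist(fps@features, use.names = FALSE)))
  # dense presence matrix over observed features only
  M <- matrix(FALSE, nrow = n, ncol = length(observed))
  colIdx <- seq_along(observed)
  names(colIdx) <- observed
  for (i in seq_len(n)) {
    f <- fps@features[[i]]
    if (length(f)) M[i, colIdx[as.character(f)]] <- TRUE
  }
  isAct <- labels == 1L

  nodes <- list()
  addNode <- function(rows, depth) {
    id <- length(nodes) + 1L
    nT <- length(rows); nA <- sum(isAct[rows])
    node <- list(node = id, feature = NA_integer_, absent = NA_integer_,
                 present = NA_integer_, nActive = nA, nTotal = nT, leaf = TRUE)
    nodes[[id]] <<- node
    pure <- nA == 0L || nA == nT
    if (!pure && depth < maxDepth && nT >= 2L * minSamplesPerNode) {
      sub <- M[rows, , drop = FALSE]
      nPresent <- colSums(sub)
      aPresent <- colSums(sub & isAct[rows])
      valid <- which(nPresent >= minSamplesPerNode &
                     (nT - nPresent) >= minSamplesPerNode)
      if (length(valid)) {
        parent <- giniImpurity(nA, nT)
        dec <- vapply(valid, function(j) {
          n1 <- nPresent[j]; a1 <- aPresent[j]
          parent - (n1 / nT) * giniImpurity(a1, n1) -
            ((nT - n1) / nT) * giniImpurity(nA - a1, nT - n1)
        }, numeric(1))
        # best decrease, ties by smallest feature index (valid is sorted)
        j <- valid[which.max(dec >= max(dec) - 1e-12)]
        rowsP <- rows[M[rows, j]]
        rowsA <- setdiff(rows, rowsP)
        nodes[[id]]$feature <<- observed[j]
        nodes[[id]]$leaf <<- FALSE
        nodes[[id]]$present <<- addNode(rowsP, depth + 1L)
        nodes[[id]]$absent <<- addNode(rowsA, depth + 1L)
      }
    }
    id
  }
  addNode(seq_len(n), 0L)
  tree <- do.call(rbind, lapply(nodes, function(nd)
    data.frame(node = nd$node, feature = nd$feature, absent = nd$absent,
               present = nd$present, nActive = nd$nActive, nTotal = nd$nTotal,
               leaf = nd$leaf)))
  new("RPModel", tree = tree, maxDepth = as.integer(maxDepth),
      minSamples = as.integer(minSamplesPerNode), scheme = fps@scheme,
      nbits = fps@nbits)
}

rpLeafFor <- function(model, feats) {
  tr <- model@tree
  id <- 1L
  repeat {
    row <- tr[id, ]
    if (row$leaf) return(row)
    id <- if (row$feature %in% feats) row$present else row$absent
  }
}

#' @rdname modelScores
#' @export
setMethod("modelScores", signature("RPModel", "FingerprintSet"),
  function(model, fps) {
    checkSchemeMatch(model, fps)
    vapply(fps@features, function(f) {
      leaf <- rpLeafFor(model, f)
      leaf$nActive / leaf$nTotal
    }, numeric(1))
  })

#' @rdname modelPredict
#' @export
setMethod("modelPredict", signature("RPModel", "FingerprintSet"),
  function(model, fps) {
    s <- modelScores(model, fps)
    ifelse(s > 0.5, 1L, -1L)
  })

#' Predict with a recursive-partitioning tree, returning leaf composition
#'
#' @param model a trained [RPModel-class].
#' @param fps a [FingerprintSet-class].
#' @return data.frame with `label` (majority class at the leaf, ties to -1)
#'   and `activeFraction` (leaf active proportion, usable as ROC score).
#' @export
predictRP <- function(model, fps) {
  checkSchemeMatch(model, fps)
  res <- lapply(fps@features, function(f) rpLeafFor(model, f))
  frac <- vapply(res, function(l) l$nActive / l$nTotal, numeric(1))
  data.frame(compound_id = fps@ids,
             label = ifelse(frac > 0.5, 1L, -1L),
             activeFraction = frac)
}

# ---- Serialization ---------------------------------------------------------

MODEL_FORMAT_VERSION <- 1L

#' @rdname saveModel
#' @export
setMethod("saveModel", "NBModel", function(model, path) {
  obj <- list(format_version = MODEL_FORMAT_VERSION, algorithm = "nb",
              scheme = model@scheme, nbits = model@nbits,
              prior = model@prior, threshold = model@threshold,
              feature_weights = as.list(model@weights),
              training_summary = list(n_train = model@nTrain,
                                      n_active = model@nActive))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
})

#' @rdname saveModel
#' @export
setMethod("saveModel", "RPModel", function(model, path) {
  obj <- list(format_version = MODEL_FORMAT_VERSION, algorithm = "rp",
              scheme = model@scheme, nbits = model@nbits,
              max_depth = model@maxDepth, min_samples = model@minSamples,
              nodes = model@tree)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
})

#' Load a serialized classifier
#'
#' Reads the versioned JSON written by [saveModel()]; scores and predictions
#' of the loaded model are bit-identical to the original. Corrupted or
#' version-mismatched files raise an error rather than yielding a partial
#' model.
#'
#' @param path model file.
#' @return an [NBModel-class] or [RPModel-class].
#' @export
loadModel <- function(path) {
  obj <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e)
                    stop("cannot read model file ", path, ": ",
                         conditionMessage(e)))
  if (is.null(obj$format_version) || obj$format_version != MODEL_FORMAT_VERSION)
    stop("unsupported model format version in ", path)
  if (identical(obj$algorithm, "nb")) {
    w <- unlist(obj$feature_weights)
    if (is.null(w)) w <- numeric(0)
    return(new("NBModel", prior = obj$prior, weights = w,
               nTrain = as.integer(obj$training_summary$n_train),
               nActive = as.integer(obj$training_summary$n_active),
               scheme = obj$scheme, nbits = as.integer(obj$nbits),
               threshold = obj$threshold))
  }
  if (identical(obj$algorithm, "rp")) {
    tr <- as.data.frame(obj$nodes)
    tr$feature <- as.integer(tr$feature)
    return(new("RPModel", tree = tr, maxDepth = as.integer(obj$max_depth),
               minSamples = as.integer(obj$min_samples),
               scheme = obj$scheme, nbits = as.integer(obj$nbits)))
  }
  stop("unknown algorithm in model file: ", obj$algorithm %||% "<missing>")
}

setMethod("show", "NBModel", function(object) {
  cat(sprintf(
    "NBModel (%s/%d): %d features, prior %.3f, threshold %.3g, n=%d\n",
    object@scheme, object@nbits, length(object@weights), object@prior,
    object@threshold, object@nTrain))
  invisible(NULL)
})

setMethod("show", "RPModel", function(object) {
  cat(sprintf("RPModel (%s/%d): %d nodes (%d leaves), maxDepth %d\n",
              object@scheme, object@nbits, nrow(object@tree),
              sum(object@tree$leaf), object@maxDepth))
  invisible(NULL)
})
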