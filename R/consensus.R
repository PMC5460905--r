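# Consensus chemical-protein interaction calling: a compound-target pair is
# a predicted interaction iff at least 2 of the 4 single classifiers
# (NB_ECFP6, NB_MACCS, RP_ECFP6, RP_MACCS) vote active.

VOTE_ORDER <- c("nb_ecfp6", "nb_maccs", "rp_ecfp6", "rp_maccs")
CONSENSUS_MIN_VOTES <- 2L

#' Consensus interaction call from four classifier votes
#'
#' @param votes numeric/logical vector of exactly four binary votes, in the
#'   fixed order NB_ECFP6, NB_MACCS, RP_ECFP6, RP_MACCS (1/TRUE = active).
#'   The rule itself is order-invariant; the order fixes serialization.
#' @return list with `votes` (named 0/1 vector), `n_active_votes` and
#'   `interaction` (TRUE iff at least two active votes).
#' @examples
#' consensusCall(c(1, 1, 0, 0))$interaction  # TRUE: two of four suffice
#' consensusCall(c(0, 0, 0, 0))$interaction  # FALSE
#' @export
consensusCall <- function(votes) {
  if (length(votes) != 4L || any(is.na(votes)))
    stop("exactly 4 non-missing classifier votes are required")
  v <- as.integer(as.logical(votes))
  if (any(is.na(v))) stop("votes must be binary (0/1 or logical)")
  names(v) <- VOTE_ORDER
  nAct <- sum(v)
  list(votes = v, n_active_votes = nAct,
       interaction = nAct >= CONSENSUS_MIN_VOTES)
}

#' Train the four-classifier quartet for one target
#'
#' Trains NB and RP models on both fingerprint schemes from the training
#' side of a modelling set.
#'
#' @param ms a [ModelingSet-class] with a split assignment (or without, in
#'   which case all compounds train).
#' @param nbits folded length for the circular fingerprints.
#' @param maxDepth,minSamplesPerNode recursive-partitioning parameters.
#' @return named list of four models (`nb_ecfp6`, `nb_maccs`, `rp_ecfp6`,
#'   `rp_maccs`).
#' @export
trainClassifierQuartet <- function(ms, nbits = 2048L, maxDepth = 20L,
                                   minSamplesPerNode = 10L) {
  cs <- if (length(ms@split)) msCompounds(ms, "train") else msCompounds(ms)
  labels <- cs@label
  fpsE <- computeFingerprints(cs, "ECFP6", nbits = nbits)
  fpsM <- computeFingerprints(cs, "MACCS166")
  list(nb_ecfp6 = trainNaiveBayes(fpsE, labels),
       nb_maccs = trainNaiveBayes(fpsM, labels),
       rp_ecfp6 = trainRecursivePartitioning(fpsE, labels, maxDepth,
                                             minSamplesPerNode),
       rp_maccs = trainRecursivePartitioning(fpsM, labels, maxDepth,
                                             minSamplesPerNode))
}

checkQuartet <- function(models, target) {
  missing <- setdiff(VOTE_ORDER, names(models))
  if (length(missing))
    stop("incomplete model quartet for target ", target, ": missing ",
         paste(missing, collapse = ", "))
  invisible(models)
}

#' Multi-target consensus prediction profile
#'
#' Applies every target's classifier quartet to each compound and makes the
#' 2-of-4 consensus interaction call per compound-target pair. Fingerprints
#' are computed once per scheme and reused across all targets.
#'
#' @param compounds a [CompoundSet-class] (standardized).
#' @param modelLibrary named list: target id -> list of four models as
#'   returned by [trainClassifierQuartet()].
#' @return data.frame with one row per compound-target pair: `compound_id`,
#'   `target_id`, the four vote columns, `n_active_votes`, `interaction`.
#' @export
predictProfile <- function(compounds, modelLibrary) {
  stopifnot(is(compounds, "CompoundSet"))
  if (!length(modelLibrary)) stop("empty model library")
  for (tg in names(modelLibrary)) checkQuartet(modelLibrary[[tg]], tg)
  ref <- modelLibrary[[1]]
  fpsE <- computeFingerprints(compounds, ref$nb_ecfp6@scheme,
                              nbits = ref$nb_ecfp6@nbits)
  fpsM <- computeFingerprints(compounds, "MACCS166")
  rows <- lapply(names(modelLibrary), function(tg) {
    m <- modelLibrary[[tg]]
    votes <- cbind(
      nb_ecfp6 = modelPredict(m$nb_ecfp6, fpsE) == 1L,
      nb_maccs = modelPredict(m$nb_maccs, fpsM) == 1L,
      rp_ecfp6 = modelPredict(m$rp_ecfp6, fpsE) == 1L,
      rp_maccs = modelPredict(m$rp_maccs, fpsM) == 1L)
    nAct <- rowSums(votes)
    data.frame(compound_id = compounds@compoundId, target_id = tg,
               nb_ecfp6 = as.integer(votes[, 1]),
               nb_maccs = as.integer(votes[, 2]),
               rp_ecfp6 = as.integer(votes[, 3]),
               rp_maccs = as.integer(votes[, 4]),
               n_active_votes = as.integer(nAct),
               interaction = nAct >= CONSENSUS_MIN_VOTES,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write consensus predictions as CSV
#'
#' @param profile data.frame from [predictProfile()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writePredictions <- function(profile, path) {
  utils::write.csv(profile, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
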