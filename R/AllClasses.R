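#' @import methods
NULL

#' CompoundSet: a collection of small molecules with activity annotations
#'
#' Container for compound records used throughout the package: an identifier,
#' a SMILES structure (canonical after [standardizeCompounds()]), an optional
#' activity value in nM (Ki, IC50 or EC50), and a class label (+1 active,
#' -1 decoy, NA unlabeled).
#'
#' @slot compoundId character vector of unique identifiers.
#' @slot smiles character vector of SMILES strings, parallel to `compoundId`.
#' @slot activity numeric vector of activity values in nM (NA when absent).
#' @slot activityType character vector; one of `"Ki"`, `"IC50"`, `"EC50"`,
#'   `"none"`.
#' @slot label integer vector; `+1L` active, `-1L` decoy, `NA` unlabeled.
#' @slot stdLog data.frame log of standardization events (drops/merges),
#'   filled by [standardizeCompounds()].
#'
#' @seealso [CompoundSet()], [standardizeCompounds()], [labelByActivity()]
#' @exportClass CompoundSet
setClass("CompoundSet",
  representation(
    compoundId   = "character",
    smiles       = "character",
    activity     = "numeric",
    activityType = "character",
    label        = "integer",
    stdLog       = "data.frame"
  ),
  prototype(stdLog = data.frame(compound_id = character(), event = character(),
                                detail = character(), stringsAsFactors = FALSE))
)

setValidity("CompoundSet", function(object) {
  n <- length(object@compoundId)
  if (length(object@smiles) != n || length(object@activity) != n ||
      length(object@activityType) != n || length(object@label) != n)
    return("all slots must have the same length")
  if (anyDuplicated(object@compoundId))
    return("compound ids must be unique")
  if (!all(object@activityType %in% c("Ki", "IC50", "EC50", "none")))
    return("activityType must be one of Ki, IC50, EC50, none")
  bad <- !is.na(object@label) & !(object@label %in% c(1L, -1L))
  if (any(bad)) return("labels must be +1, -1 or NA")
  if (any(!is.na(object@activity) & object@activity <= 0))
    return("activity values must be positive (nM)")
  TRUE
})

#' FingerprintSet: binary molecular fingerprints for a set of compounds
#'
#' Sparse representation of binary fingerprints: for each compound the set of
#' on-feature indices (0-based) under one scheme. Circular schemes (ECFP2,
#' ECFP6) are hashed atom-environment fingerprints folded to `nbits`;
#' MACCS166 is the 166-key structural dictionary (index = key number - 1).
#'
#' @slot scheme one of `"ECFP2"`, `"ECFP6"`, `"MACCS166"`.
#' @slot nbits integer fingerprint length (166 for MACCS166).
#' @slot features list of sorted integer vectors of on-feature indices.
#' @slot ids character vector of compound ids, parallel to `features`.
#'
#' @seealso [computeFingerprints()], [tanimoto()], [diversityIndex()]
#' @exportClass FingerprintSet
setClass("FingerprintSet",
  representation(
    scheme   = "character",
    nbits    = "integer",
    features = "list",
    ids      = "character"
  )
)

setValidity("FingerprintSet", function(object) {
  if (!object@scheme %in% c("ECFP2", "ECFP6", "MACCS166"))
    return("scheme must be ECFP2, ECFP6 or MACCS166")
  if (object@scheme == "MACCS166" && object@nbits != 166L)
    return("MACCS166 fingerprints must have length 166")
  if (length(object@features) != length(object@ids))
    return("features and ids must be parallel")
  for (f in object@features) {
    if (length(f) && (any(f < 0L) || any(f >= object@nbits)))
      return("on-feature indices must lie in [0, nbits)")
  }
  TRUE
})

#' NBModel: Laplacian-corrected naive Bayes classifier over fingerprints
#'
#' Trained model of the Laplacian-corrected ("relative frequency") naive
#' Bayes classifier used for ligand-based target prediction. For a feature f
#' seen in `T_f` training compounds of which `A_f` are active, the model
#' stores the log-weight `W_f = log((A_f + 1) / (T_f * P + 1))` where `P` is
#' the prior active fraction. A compound's score is the sum of weights of its
#' on-features; it is classified active when the score exceeds `threshold`.
#'
#' @slot prior numeric, training active fraction P(+).
#' @slot weights named numeric vector of per-feature log-weights; names are
#'   0-based feature indices.
#' @slot nTrain integer number of training compounds.
#' @slot nActive integer number of training actives.
#' @slot scheme fingerprint scheme the model consumes.
#' @slot nbits fingerprint length the model consumes.
#' @slot threshold numeric decision cutoff on the additive score.
#'
#' @seealso [trainNaiveBayes()], [modelScores()], [topFeatures()]
#' @exportClass NBModel
setClass("NBModel",
  representation(
    prior     = "numeric",
    weights   = "numeric",
    nTrain    = "integer",
    nActive   = "integer",
    scheme    = "character",
    nbits     = "integer",
    threshold = "numeric"
  )
)

setValidity("NBModel", function(object) {
  if (object@prior <= 0 || object@prior >= 1)
    return("prior active fraction must lie in (0, 1)")
  if (length(object@weights) && is.null(names(object@weights)))
    return("weights must be named by feature index")
  if (any(!is.finite(object@weights)))
    return("all feature weights must be finite")
  TRUE
})

#' RPModel: recursive-partitioning decision tree over fingerprint bits
#'
#' Binary decision tree classifying compounds by presence/absence of single
#' fingerprint features, grown greedily by Gini impurity decrease. The tree
#' is stored as a node table; leaves carry class counts so predictions can
#' return the leaf active fraction as a ranking score.
#'
#' @slot tree data.frame with one row per node: `node`, `feature` (split
#'   feature index, NA at leaves), `absent`/`present` (child node ids),
#'   `nActive`, `nTotal`, `leaf`.
#' @slot maxDepth integer depth cap used at training.
#' @slot minSamples integer minimum compounds per node.
#' @slot scheme,nbits fingerprint scheme/length the model consumes.
#'
#' @seealso [trainRecursivePartitioning()], [modelPredict()]
#' @exportClass RPModel
setClass("RPModel",
  representation(
    tree       = "data.frame",
    maxDepth   = "integer",
    minSamples = "integer",
    scheme     = "character",
    nbits      = "integer"
  )
)

setValidity("RPModel", function(object) {
  tr <- object@tree
  need <- c("node", "feature", "absent", "present", "nActive", "nTotal", "leaf")
  if (!all(need %in% names(tr))) return("tree table missing required columns")
  if (any(tr$nTotal <= 0)) return("every node must contain compounds")
  TRUE
})

#' ModelingSet: actives, decoys and the train/test split for one target
#'
#' Per-target modelling data: labelled actives (+1), sampled decoys (-1) at a
#' fixed decoy:active ratio, and a stratified train/test assignment.
#'
#' @slot target list with at least `gene_symbol`; optionally `protein_name`,
#'   `uniprot_id`, `subfamily`.
#' @slot actives,decoys [CompoundSet] objects (disjoint by structure).
#' @slot split named character vector mapping compound id to `"train"` or
#'   `"test"`.
#' @slot decoyRatio numeric decoys-per-active ratio (default study design: 3).
#' @slot seed integer seed the set was built with.
#'
#' @seealso [makeSyntheticBenchmark()], [sampleDecoys()], [splitTrainTest()]
#' @exportClass ModelingSet
setClass("ModelingSet",
  representation(
    target     = "list",
    actives    = "CompoundSet",
    decoys     = "CompoundSet",
    split      = "character",
    decoyRatio = "numeric",
    seed       = "integer"
  )
)

setValidity("ModelingSet", function(object) {
  na <- length(object@actives@compoundId)
  nd <- length(object@decoys@compoundId)
  if (na > 0 && nd != object@decoyRatio * na)
    return(sprintf("expected %d decoys for %d actives (ratio %g), got %d",
                   as.integer(object@decoyRatio * na), na, object@decoyRatio, nd))
  if (length(intersect(object@actives@smiles, object@decoys@smiles)))
    return("actives and decoys overlap by structure")
  ids <- c(object@actives@compoundId, object@decoys@compoundId)
  if (length(object@split)) {
    if (!all(names(object@split) %in% ids))
      return("split references unknown compound ids")
    if (!all(object@split %in% c("train", "test")))
      return("split values must be 'train' or 'test'")
  }
  TRUE
})

#' CPINetwork: bipartite compound-target network with mechanism annotations
#'
#' Graph built from positive consensus interaction calls: compound and target
#' nodes joined by interaction edges, plus annotation edges from targets to
#' mechanism-class nodes. Mechanism nodes never enter degree statistics.
#'
#' @slot graph an igraph object with vertex attribute `type` in
#'   `{"compound","target","mechanism"}` and edge attribute `relation`.
#' @slot compounds,targets,mechanisms character vectors of node names.
#'
#' @seealso [buildNetwork()], [networkStats()], [exportSIF()]
#' @exportClass CPINetwork
setClass("CPINetwork",
  representation(
    graph      = "ANY",
    compounds  = "character",
    targets    = "character",
    mechanisms = "character"
  )
)
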