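#' @rdname CompoundSet
#' @param x,object a `CompoundSet`
#' @export
setGeneric("compoundIds", function(x) standardGeneric("compoundIds"))

#' @rdname CompoundSet
#' @export
setGeneric("compoundSmiles", function(x) standardGeneric("compoundSmiles"))

#' @rdname CompoundSet
#' @export
setGeneric("activityValues", function(x) standardGeneric("activityValues"))

#' @rdname CompoundSet
#' @export
setGeneric("compoundLabels", function(x) standardGeneric("compoundLabels"))

#' @rdname CompoundSet
#' @export
setGeneric("standardizationLog", function(x) standardGeneric("standardizationLog"))

#' @rdname FingerprintSet
#' @export
setGeneric("fpScheme", function(x) standardGeneric("fpScheme"))

#' @rdname FingerprintSet
#' @export
setGeneric("fpLength", function(x) standardGeneric("fpLength"))

#' @rdname FingerprintSet
#' @export
setGeneric("featureList", function(x) standardGeneric("featureList"))

#' Tanimoto similarity between two fingerprints
#'
#' `|a intersect b| / |a union b|` over on-features. Both fingerprints must
#' share scheme and length. By convention two empty fingerprints have
#' similarity 1.
#'
#' @param a,b single-compound [FingerprintSet] objects (or integer vectors of
#'   on-feature indices).
#' @return numeric in `[0, 1]`.
#' @export
setGeneric("tanimoto", function(a, b) standardGeneric("tanimoto"))

#' Continuous classifier scores for a fingerprint set
#'
#' For an [NBModel], the additive sum of per-feature log-weights; for an
#' [RPModel], the active fraction at the leaf each compound reaches. Both are
#' usable as ROC ranking scores.
#'
#' @param model a trained [NBModel] or [RPModel].
#' @param fps a [FingerprintSet] matching the model's scheme and length.
#' @return numeric vector of scores, one per compound.
#' @export
setGeneric("modelScores", function(model, fps) standardGeneric("modelScores"))

#' Binary class predictions for a fingerprint set
#'
#' @param model a trained [NBModel] or [RPModel].
#' @param fps a [FingerprintSet] matching the model's scheme and length.
#' @return integer vector of `+1` / `-1` predictions.
#' @export
setGeneric("modelPredict", function(model, fps) standardGeneric("modelPredict"))

#' Serialize a trained model to versioned JSON
#'
#' @param model a trained [NBModel] or [RPModel].
#' @param path file path to write.
#' @return `path`, invisibly.
#' @seealso [loadModel()]
#' @export
setGeneric("saveModel", function(model, path) standardGeneric("saveModel"))
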