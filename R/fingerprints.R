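# Circular (ECFP-style) and 166-key structural fingerprints.
#
# The circular fingerprint is computed in-package over the molecular graph
# parsed by ChemmineR/OpenBabel: per-atom initial invariants are iteratively
# combined with neighbour identifiers (Morgan-style), and every intermediate
# identifier is hashed with a fixed 31-bit integer hash so feature ids are
# stable across runs and platforms. Keeping the implementation in-package
# also preserves the feature -> atom-environment mapping needed to interpret
# naive Bayes feature weights (see ecfpEnvironments()).

DEFAULT_VALENCE <- c(H = 1, B = 3, C = 4, N = 3, O = 2, F = 1, Si = 4,
                     P = 3, S = 2, Cl = 1, Br = 1, I = 1)
ATOMIC_NUMBER <- c(H = 1, B = 5, C = 6, N = 7, O = 8, F = 9, Si = 14,
                   P = 15, S = 16, Cl = 17, Br = 35, I = 53)

# Single heavy-atom molecules (e.g. methane, water) come back from the
# SDF round-trip without a usable atom block; recover the element from the
# OpenBabel molecular formula instead.
singleAtomGraph <- function(smi) {
  formula <- tryCatch(ChemmineOB::prop_OB(
    ChemmineOB::forEachMol("SMILES", smi, identity))$formula,
    error = function(e) NULL)
  if (is.null(formula)) return(NULL)
  toks <- regmatches(formula, gregexpr("[A-Z][a-z]?", formula))[[1]]
  heavy <- setdiff(toks, "H")
  if (length(heavy) != 1L) return(NULL)
  sym <- heavy[1]
  z <- ATOMIC_NUMBER[sym]
  val <- DEFAULT_VALENCE[sym]
  list(n = 1L, symbols = sym, z = unname(if (is.na(z)) 0 else z),
       bonds = data.frame(a1 = integer(), a2 = integer(), order = integer()),
       degree = 0L, hcount = unname(if (is.na(val)) 0 else val),
       inRing = FALSE)
}

# Parse one SMILES into a light molecular graph: element symbols, bonds with
# (kekulized) orders, heavy-atom degree, implicit H count and ring membership.
parseMolGraph <- function(smi) {
  sdf <- tryCatch(suppressWarnings(ChemmineR::smiles2sdf(smi)),
                  error = function(e) NULL)
  if (is.null(sdf)) return(NULL)
  mol <- sdf[[1]]
  ab <- ChemmineR::atomblock(mol)
  if (is.null(ab) || nrow(ab) == 0) return(NULL)
  if (!any(grepl("_", rownames(ab), fixed = TRUE)))
    return(singleAtomGraph(smi))  # bond-free SDF: ChemmineR mangles it
  symbols <- sub("_.*$", "", rownames(ab))
  nA <- length(symbols)
  bb <- ChemmineR::bondblock(mol)
  if (is.null(bb) || nrow(bb) == 0 || ncol(bb) < 3) {
    bonds <- data.frame(a1 = integer(), a2 = integer(), order = integer())
  } else {
    bonds <- data.frame(a1 = as.integer(bb[, 1]), a2 = as.integer(bb[, 2]),
                        order = as.integer(bb[, 3]))
  }
  deg <- tabulate(c(bonds$a1, bonds$a2), nbins = nA)
  ordSum <- numeric(nA)
  for (k in seq_len(nrow(bonds))) {
    ordSum[bonds$a1[k]] <- ordSum[bonds$a1[k]] + bonds$order[k]
    ordSum[bonds$a2[k]] <- ordSum[bonds$a2[k]] + bonds$order[k]
  }
  val <- DEFAULT_VALENCE[symbols]
  val[is.na(val)] <- 0
  hcount <- pmax(0, val - ordSum)
  inRing <- rep(FALSE, nA)
  if (nrow(bonds) > 0) {
    g <- igraph::graph_from_edgelist(cbind(bonds$a1, bonds$a2), directed = FALSE)
    br <- igraph::bridges(g)
    ringEdge <- setdiff(seq_len(nrow(bonds)), as.integer(br))
    inRing[unique(c(bonds$a1[ringEdge], bonds$a2[ringEdge]))] <- TRUE
  }
  z <- ATOMIC_NUMBER[symbols]
  z[is.na(z)] <- 0
  list(n = nA, symbols = symbols, z = unname(z), bonds = bonds,
       degree = deg, hcount = unname(hcount), inRing = inRing)
}

# Circular atom-environment features for one parsed molecule.
# Returns identifiers plus, per feature, the centre atom, radius, and the set
# of atoms the environment spans.
ecfpFromGraph <- function(g, radius) {
  nA <- g$n
  nbrs <- vector("list", nA)
  if (nrow(g$bonds)) {
    for (k in seq_len(nrow(g$bonds))) {
      a <- g$bonds$a1[k]; b <- g$bonds$a2[k]; o <- g$bonds$order[k]
      nbrs[[a]] <- rbind(nbrs[[a]], c(b, o))
      nbrs[[b]] <- rbind(nbrs[[b]], c(a, o))
    }
  }
  ids <- vapply(seq_len(nA), function(i)
    hashInts(c(g$z[i], g$degree[i], g$hcount[i], as.integer(g$inRing[i]))),
    numeric(1))
  span <- as.list(seq_len(nA))
  feats <- data.frame(id = ids, center = seq_len(nA), radius = 0L)
  atomSets <- span
  if (radius > 0 && nA > 1) {
    for (r in seq_len(radius)) {
      newIds <- ids
      newSpan <- span
      for (i in seq_len(nA)) {
        nb <- nbrs[[i]]
        if (is.null(nb)) next
        ord <- order(nb[, 2], ids[nb[, 1]])
        pairs <- as.vector(t(cbind(nb[ord, 2], ids[nb[ord, 1]])))
        newIds[i] <- hashInts(c(r, ids[i], pairs))
        newSpan[[i]] <- sort(unique(c(span[[i]], unlist(span[nb[, 1]]))))
      }
      ids <- newIds
      span <- newSpan
      feats <- rbind(feats,
                     data.frame(id = ids, center = seq_len(nA), radius = r))
      atomSets <- c(atomSets, span)
    }
  }
  list(features = feats, atomSets = atomSets)
}

ecfpRadius <- function(scheme) switch(scheme, ECFP2 = 1L, ECFP6 = 3L,
                                      stop("not a circular scheme: ", scheme))

maccsOnKeys <- function(smi) {
  mol <- tryCatch(ChemmineOB::forEachMol("SMILES", smi, identity),
                  error = function(e) NULL)
  fp <- tryCatch(ChemmineOB::fingerprint_OB(mol, "MACCS"),
                 error = function(e) NULL)
  if (is.null(fp) || !length(fp)) return(NULL)
  on <- which(fp != 0)
  on <- on[on <= 166L]   # keys are numbered 1..166 within the padded block
  as.integer(on)
}

#' Compute molecular fingerprints for a compound collection
#'
#' Supports two circular schemes (`ECFP2`: diameter 2 / radius 1, `ECFP6`:
#' diameter 6 / radius 3) hashed and folded to `nbits` bits, and the 166-key
#' structural dictionary (`MACCS166`, computed with OpenBabel; stored as
#' 0-based key indices). Feature sets are deterministic: the same molecule,
#' scheme and parameters always yield the identical fingerprint.
#'
#' @param x a [CompoundSet-class] or character vector of SMILES.
#' @param scheme `"ECFP6"`, `"ECFP2"` or `"MACCS166"`.
#' @param nbits folded length for circular schemes (default 2048; ignored for
#'   MACCS166).
#' @param folded if `FALSE`, circular features keep their unfolded 31-bit
#'   sparse identifiers (`nbits` becomes `2^31 - 1`).
#' @return a [FingerprintSet-class].
#' @examples
#' fps <- computeFingerprints(c(benzene = "c1ccccc1", hexane = "C1CCCCC1"),
#'                            scheme = "ECFP6")
#' lengths(featureList(fps))
#' @export
computeFingerprints <- function(x, scheme = c("ECFP6", "ECFP2", "MACCS166"),
                                nbits = 2048L, folded = TRUE) {
  scheme <- match.arg(scheme)
  if (is(x, "CompoundSet")) {
    smiles <- x@smiles
    ids <- x@compoundId
  } else {
    smiles <- as.character(x)
    ids <- names(x) %||% sprintf("cmpd_%04d", seq_along(smiles))
    if (is.null(names(x)) || any(!nzchar(ids)))
      ids <- sprintf("cmpd_%04d", seq_along(smiles))
  }
  if (scheme == "MACCS166") {
    feats <- lapply(seq_along(smiles), function(i) {
      on <- maccsOnKeys(smiles[i])
      if (is.null(on))
        stop("invalid structure for compound ", ids[i], ": ", smiles[i])
      sort(on - 1L)
    })
    return(new("FingerprintSet", scheme = scheme, nbits = 166L,
               features = feats, ids = ids))
  }
  rad <- ecfpRadius(scheme)
  if (!folded) nbits <- 2147483647L
  nbits <- as.integer(nbits)
  feats <- lapply(seq_along(smiles), function(i) {
    g <- parseMolGraph(smiles[i])
    if (is.null(g))
      stop("invalid structure for compound ", ids[i], ": ", smiles[i])
    idv <- unique(ecfpFromGraph(g, rad)$features$id)
    sort(unique(as.integer(idv %% nbits)))
  })
  new("FingerprintSet", scheme = scheme, nbits = nbits,
      features = feats, ids = ids)
}

#' Circular atom environments behind each fingerprint feature
#'
#' Exposes the feature -> atom mapping of the circular fingerprint for one
#' molecule: each row gives a (folded) feature index, its centre atom, the
#' environment radius, and the atom indices the environment spans (atom
#' numbering follows SMILES order). Used to interpret top-ranked naive Bayes
#' features, e.g. to check that a highly weighted feature sits inside an
#' enriched scaffold.
#'
#' @param smi a single SMILES string.
#' @param scheme `"ECFP6"` or `"ECFP2"`.
#' @param nbits folded length (must match the fingerprints being interpreted).
#' @return data.frame with columns `feature`, `center`, `radius` and a list
#'   column `atoms`.
#' @export
ecfpEnvironments <- function(smi, scheme = c("ECFP6", "ECFP2"), nbits = 2048L) {
  scheme <- match.arg(scheme)
  g <- parseMolGraph(smi)
  if (is.null(g)) stop("invalid structure: ", smi)
  res <- ecfpFromGraph(g, ecfpRadius(scheme))
  out <- res$features
  out$feature <- as.integer(out$id %% as.integer(nbits))
  out$atoms <- I(res$atomSets)
  out[, c("feature", "center", "radius", "atoms")]
}

#' @rdname FingerprintSet
#' @export
setMethod("fpScheme", "FingerprintSet", function(x) x@scheme)

#' @rdname FingerprintSet
#' @export
setMethod("fpLength", "FingerprintSet", function(x) x@nbits)

#' @rdname FingerprintSet
#' @export
setMethod("featureList", "FingerprintSet", function(x) {
  structure(x@features, names = x@ids)
})

#' @rdname FingerprintSet
#' @param x,object a `FingerprintSet`
#' @export
setMethod("length", "FingerprintSet", function(x) length(x@features))

#' @rdname FingerprintSet
#' @param i index vector
#' @param j,drop,... ignored
#' @export
setMethod("[", "FingerprintSet", function(x, i, j, ..., drop = TRUE) {
  if (is.character(i)) i <- match(i, x@ids)
  initialize(x, features = x@features[i], ids = x@ids[i])
})

setMethod("show", "FingerprintSet", function(object) {
  cat(sprintf("FingerprintSet: %d compounds, scheme %s, length %d\n",
              length(object@features), object@scheme, object@nbits))
  if (length(object@features))
    cat(sprintf("  on-bits per compound: median %g (range %d-%d)\n",
                stats::median(lengths(object@features)),
                min(lengths(object@features)), max(lengths(object@features))))
  invisible(NULL)
})

tanimotoSets <- function(a, b) {
  ni <- length(intersect(a, b))
  nu <- length(a) + length(b) - ni
  if (nu == 0) 1 else ni / nu
}

#' @rdname tanimoto
#' @export
setMethod("tanimoto", signature("FingerprintSet", "FingerprintSet"),
  function(a, b) {
    if (a@scheme != b@scheme || a@nbits != b@nbits)
      stop("fingerprint scheme/length mismatch: ", a@scheme, " vs ", b@scheme)
    if (length(a@features) != 1L || length(b@features) != 1L)
      stop("tanimoto() compares two single-compound fingerprint sets")
    tanimotoSets(a@features[[1]], b@features[[1]])
  })

#' @rdname tanimoto
#' @export
setMethod("tanimoto", signature("integer", "integer"),
  function(a, b) tanimotoSets(a, b))

#' Mean pairwise Tanimoto diversity of a compound set
#'
#' Mean Tanimoto similarity over all unordered distinct pairs, conventionally
#' computed on the diameter-2 circular fingerprint. Smaller values indicate a
#' more structurally diverse set.
#'
#' @param x a [CompoundSet-class], character vector of SMILES, or a
#'   precomputed [FingerprintSet-class].
#' @param scheme fingerprint scheme when `x` holds structures.
#' @return list with `n_compounds`, `mean_pairwise_tanimoto` and `scheme`.
#' @export
diversityIndex <- function(x, scheme = "ECFP2") {
  fps <- if (is(x, "FingerprintSet")) x else computeFingerprints(x, scheme)
  n <- length(fps@features)
  if (n < 2) stop("diversity index requires at least 2 compounds")
  total <- 0
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      total <- total + tanimotoSets(fps@features[[i]], fps@features[[j]])
    }
  }
  list(n_compounds = n,
       mean_pairwise_tanimoto = total / (n * (n - 1) / 2),
       scheme = fps@scheme)
}

#' Export fingerprints as a sparse index CSV
#'
#' One row per compound: `compound_id`, `scheme`, and the on-feature indices
#' joined by semicolons.
#'
#' @param fps a [FingerprintSet-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
exportFingerprints <- function(fps, path) {
  df <- data.frame(compound_id = fps@ids, scheme = fps@scheme,
                   features = vapply(fps@features, paste,
                                     character(1), collapse = ";"),
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
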