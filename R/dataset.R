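# Per-target modelling sets: decoy sampling, train/test splits, and the
# fully synthetic benchmark generator.

#' The seven mechanism classes of the AD target library
#'
#' Fixed subfamily vocabulary for target annotation: modulation of
#' neurotransmission, tau pathology, amyloid-beta-related approaches,
#' intracellular signalling cascades, anti-inflammatory approaches,
#' mitochondrial dysfunction and metabolic dysfunction.
#'
#' @export
mechanismClasses <- c("neurotransmission", "tau_pathology", "abeta_related",
                      "intracellular_signalling", "anti_inflammatory",
                      "mitochondrial_dysfunction", "metabolic_dysfunction")

#' Validate a target metadata table
#'
#' Checks a data.frame of target records: unique `gene_symbol`, and every
#' `subfamily` annotation drawn from [mechanismClasses]. A target may belong
#' to several subfamilies (semicolon-separated).
#'
#' @param df data.frame with columns `gene_symbol`, `subfamily` and
#'   optionally `protein_name`, `uniprot_id`.
#' @return the validated data.frame, invisibly.
#' @export
validateTargetTable <- function(df) {
  if (!all(c("gene_symbol", "subfamily") %in% names(df)))
    stop("target table needs columns gene_symbol and subfamily")
  if (anyDuplicated(df$gene_symbol))
    stop("gene symbols must be unique per target library")
  subs <- unlist(strsplit(df$subfamily, ";", fixed = TRUE))
  bad <- setdiff(trimws(subs), mechanismClasses)
  if (length(bad))
    stop("unknown mechanism subfamily: ", paste(bad, collapse = ", "))
  invisible(df)
}

#' Construct a ModelingSet
#'
#' @param target list or single-row data.frame of target metadata (needs
#'   `gene_symbol`).
#' @param actives a [CompoundSet-class] of actives (labels set to +1).
#' @param decoys a [CompoundSet-class] of decoys (labels set to -1).
#' @param split named character vector id -> `"train"`/`"test"` (may be
#'   filled later by [splitTrainTest()]).
#' @param decoyRatio decoys-per-active ratio the set was built at.
#' @param seed integer seed recorded for provenance.
#' @return a [ModelingSet-class].
#' @export
ModelingSet <- function(target, actives, decoys, split = character(0),
                        decoyRatio = 3, seed = NA_integer_) {
  if (is.data.frame(target)) target <- as.list(target[1, ])
  actives@label <- rep(1L, length(actives))
  decoys@label <- rep(-1L, length(decoys))
  new("ModelingSet", target = target, actives = actives, decoys = decoys,
      split = split, decoyRatio = decoyRatio, seed = as.integer(seed))
}

#' @rdname ModelingSet
#' @param x a `ModelingSet`
#' @export
msActives <- function(x) x@actives

#' @rdname ModelingSet
#' @export
msDecoys <- function(x) x@decoys

#' @rdname ModelingSet
#' @export
msSplit <- function(x) x@split

#' @rdname ModelingSet
#' @export
msTarget <- function(x) x@target

#' All compounds of a ModelingSet, optionally one split side
#'
#' @param x a [ModelingSet-class].
#' @param subset `"all"`, `"train"` or `"test"`.
#' @return a [CompoundSet-class] with labels set.
#' @export
msCompounds <- function(x, subset = c("all", "train", "test")) {
  subset <- match.arg(subset)
  a <- x@actives; d <- x@decoys
  cs <- CompoundSet(c(a@compoundId, d@compoundId), c(a@smiles, d@smiles),
                    c(a@activity, d@activity),
                    c(a@activityType, d@activityType),
                    c(a@label, d@label))
  if (subset == "all") return(cs)
  if (!length(x@split)) stop("ModelingSet has no split assignment yet")
  keep <- which(x@split[cs@compoundId] == subset)
  cs[keep]
}

setMethod("show", "ModelingSet", function(object) {
  cat(sprintf("ModelingSet '%s': %d actives, %d decoys (ratio %g)\n",
              object@target$gene_symbol %||% "?",
              length(object@actives), length(object@decoys),
              object@decoyRatio))
  if (length(object@split)) {
    tab <- table(object@split)
    cat(sprintf("  split: %d train / %d test\n",
                tab[["train"]], tab[["test"]]))
  }
  invisible(NULL)
})

#' Sample decoys for an active set from a background pool
#'
#' Draws `ratio x n_actives` presumed-inactive compounds from a background
#' library, uniformly without replacement, after excluding every pool entry
#' whose canonical structure matches an active. With `propertyMatched`,
#' sampling is stratified so the decoys' molecular-weight distribution
#' follows the actives' MW deciles (shortfalls in a decile are refilled
#' uniformly from the remaining pool).
#'
#' @param actives a [CompoundSet-class] of actives.
#' @param pool a [CompoundSet-class] background library.
#' @param ratio decoys per active (default 3).
#' @param seed integer seed.
#' @param propertyMatched logical; stratify by actives' MW deciles.
#' @return a [CompoundSet-class] of decoys with label -1.
#' @export
sampleDecoys <- function(actives, pool, ratio = 3, seed = 2017L,
                         propertyMatched = FALSE) {
  stopifnot(is(actives, "CompoundSet"), is(pool, "CompoundSet"))
  need <- ratio * length(actives)
  activeCan <- canonicalSmiles(actives@smiles)
  poolCan <- canonicalSmiles(pool@smiles)
  ok <- which(!is.na(poolCan) & !(poolCan %in% activeCan))
  if (length(ok) < need)
    stop(sprintf(
      "background pool too small: need %d decoys, only %d usable (short %d)",
      need, length(ok), need - length(ok)))
  picked <- withSeed(seed, {
    if (!propertyMatched) {
      sort(sample(ok, need))
    } else {
      mw <- function(smi) vapply(smi, function(s)
        tryCatch(ChemmineOB::prop_OB(
          ChemmineOB::forEachMol("SMILES", s, identity))$MW,
          error = function(e) NA_real_), numeric(1), USE.NAMES = FALSE)
      amw <- mw(actives@smiles)
      pmw <- mw(pool@smiles[ok])
      edges <- unique(stats::quantile(amw, probs = 0:10 / 10, na.rm = TRUE))
      edges[1] <- -Inf; edges[length(edges)] <- Inf
      abin <- cut(amw, edges, include.lowest = TRUE)
      pbin <- cut(pmw, edges, include.lowest = TRUE)
      want <- round(need * table(abin) / length(amw))
      chosen <- integer(0)
      for (b in levels(abin)) {
        inBin <- ok[which(pbin == b)]
        k <- min(want[[b]], length(inBin))
        if (k > 0) chosen <- c(chosen, sample(inBin, k))
      }
      rest <- setdiff(ok, chosen)
      if (length(chosen) < need)
        chosen <- c(chosen, sample(rest, need - length(chosen)))
      sort(chosen[seq_len(need)])
    }
  })
  out <- pool[picked]
  out@label <- rep(-1L, length(out))
  out
}

#' Stratified train/test split
#'
#' Randomly assigns compounds to training and test sets per class at
#' `ratio`:1 (default 3:1, i.e. 75% training), rounding toward the training
#' side. Deterministic under `seed`.
#'
#' @param ms a [ModelingSet-class].
#' @param ratio train:test ratio (default 3).
#' @param seed integer seed.
#' @return the [ModelingSet-class] with its `split` slot filled.
#' @export
splitTrainTest <- function(ms, ratio = 3, seed = 2017L) {
  stopifnot(is(ms, "ModelingSet"))
  groups <- list(ms@actives@compoundId, ms@decoys@compoundId)
  for (ids in groups)
    if (length(ids) < ratio + 1)
      stop("each class needs at least ratio+1 = ", ratio + 1, " compounds")
  split <- withSeed(seed, {
    out <- character(0)
    for (ids in groups) {
      n <- length(ids)
      nTrain <- ceiling(n * ratio / (ratio + 1))
      shuffled <- sample(ids)
      s <- c(rep("train", nTrain), rep("test", n - nTrain))
      names(s) <- shuffled
      out <- c(out, s)
    }
    out
  })
  ms@split <- split[c(ms@actives@compoundId, ms@decoys@compoundId)]
  ms@seed <- as.integer(seed)
  validObject(ms)
  ms
}

# ---- Synthetic benchmark ---------------------------------------------------

#' Built-in fragment vocabulary of the synthetic benchmark
#'
#' About forty chemically valid SMILES fragments whose first and last atoms
#' have free valence, so fragments can be chained into valid molecules by
#' concatenation (each chain junction becomes a single bond). `scaffolds`
#' are distinctive fused ring systems planted as per-target enrichment
#' signals; `decorations` are common rings, chains and functional groups
#' shared by actives and decoys.
#'
#' @return list with character vectors `scaffolds` and `decorations`.
#' @export
fragmentVocabulary <- function() {
  list(
    scaffolds = c(
      quinoline       = "c1ccc2ncccc2c1",
      isoquinoline    = "c1ccc2cnccc2c1",
      quinoxaline     = "c1ccc2nccnc2c1",
      naphthalene     = "c1ccc2ccccc2c1",
      anthracene      = "c1ccc2cc3ccccc3cc2c1",
      decalin         = "C1CCC2CCCCC2C1",
      benzofuran      = "c1ccc2occc2c1",
      benzothiophene  = "c1ccc2sccc2c1",
      indole          = "c1ccc2[nH]ccc2c1",
      benzodioxole    = "c1ccc2OCOc2c1",
      thiomorpholine  = "C1CSCCN1",
      piperazine      = "C1CNCCN1"
    ),
    decorations = c(
      methyl = "C", ethyl = "CC", propyl = "CCC", butyl = "CCCC",
      methoxy = "CO", ethanol = "CCO", methylamine = "CN", ethylamine = "CCN",
      isopropyl = "C(C)C", acetyl = "C(=O)C", amide = "C(=O)N",
      carboxyl = "C(=O)O",
      benzene = "c1ccccc1", toluene = "c1cc(C)ccc1", phenol = "c1cc(O)ccc1",
      aniline = "c1cc(N)ccc1", fluorobenzene = "c1cc(F)ccc1",
      chlorobenzene = "c1cc(Cl)ccc1", bromobenzene = "c1cc(Br)ccc1",
      cyclopentane = "C1CCCC1", cyclohexane = "C1CCCCC1",
      cyclopropane = "C1CC1", tetrahydropyran = "C1CCOCC1",
      morpholine = "C1COCCN1", pyridine = "c1ccncc1", pyrimidine = "c1cncnc1"
    )
  )
}

fragmentHeavyAtoms <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      voc <- fragmentVocabulary()
      all <- unname(c(voc$scaffolds, voc$decorations))
      cache <<- vapply(all, function(f) parseMolGraph(f)$n, integer(1))
      names(cache) <<- all
    }
    cache
  }
})

# Number of decoration fragments each synthetic target's actives draw from:
# actives behave like a congeneric series sharing a decoration palette (and
# usually the scaffold), while decoys sample the full vocabulary.
PALETTE_SIZE <- 10L

# Assemble a linear chain of fragments into one SMILES; returns the string
# plus the heavy-atom offset and length of the fragment named in `mark`.
assembleChain <- function(fragSmiles, mark = NA_integer_) {
  smi <- paste0(fragSmiles, collapse = "")
  offset <- NA_integer_; len <- NA_integer_
  if (!is.na(mark)) {
    nAtoms <- vapply(fragSmiles, function(f) fragmentHeavyAtoms()[[f]],
                     integer(1))
    offset <- if (mark > 1) sum(nAtoms[seq_len(mark - 1)]) else 0L
    len <- nAtoms[mark]
  }
  list(smiles = smi, scaffoldOffset = as.integer(offset),
       scaffoldLength = as.integer(len))
}

#' Generate a fully synthetic multi-target benchmark
#'
#' Emulates per-target active sets sharing enriched substructures against
#' structure-diverse decoys. For each synthetic target a private scaffold is
#' drawn from the built-in vocabulary; each active is a random chain of 2-4
#' decoration fragments drawn from a target-specific 10-fragment palette (a
#' congeneric series shares more than its core), carrying the target scaffold
#' with probability `signalStrength` at a random chain position. Decoys are
#' chains over the full decoration vocabulary, sampled into each set at
#' `decoyRatio`:1 via
#' [sampleDecoys()] (excluding any structure identical to an active), and
#' each set receives a stratified 3:1 train/test split. All emitted SMILES
#' are valid by construction (chain junctions are single bonds between atoms
#' with free valence). Byte-identical output under a fixed seed.
#'
#' @param nTargets number of synthetic targets (up to 12 scaffolds).
#' @param nActivesPerTarget actives per target (>= 20).
#' @param decoyRatio decoys per active (default 3).
#' @param signalStrength probability in (0, 1] that an active carries its
#'   target scaffold.
#' @param seed integer master seed.
#' @param splitRatio train:test ratio (default 3).
#' @return list with `sets` (named list of [ModelingSet-class]), `truth`
#'   (data.frame: target, scaffold name and SMILES), and `activeDetails`
#'   (per-active scaffold placement: compound id, carries flag, heavy-atom
#'   offset/length of the scaffold within the SMILES atom order).
#' @export
makeSyntheticBenchmark <- function(nTargets = 1L, nActivesPerTarget = 100L,
                                   decoyRatio = 3, signalStrength = 0.9,
                                   seed = 2017L, splitRatio = 3) {
  if (signalStrength <= 0 || signalStrength > 1)
    stop("signalStrength must lie in (0, 1]")
  if (nActivesPerTarget < 20) stop("need at least 20 actives per target")
  voc <- fragmentVocabulary()
  if (nTargets < 1 || nTargets > length(voc$scaffolds))
    stop("nTargets must be between 1 and ", length(voc$scaffolds))
  withSeed(seed, {
    scafIdx <- sample(length(voc$scaffolds), nTargets)
    sets <- list(); truthRows <- list(); detailRows <- list()
    for (t in seq_len(nTargets)) {
      gene <- sprintf("SYNT%02d", t)
      scaf <- voc$scaffolds[[scafIdx[t]]]
      palette <- sample(voc$decorations, PALETTE_SIZE)
      # actives: palette chains, scaffold inserted w.p. signalStrength
      smis <- character(nActivesPerTarget)
      for (i in seq_len(nActivesPerTarget)) {
        deco <- sample(palette, sample(2:4, 1), replace = TRUE)
        carries <- stats::runif(1) <= signalStrength
        if (carries) {
          pos <- sample(length(deco) + 1L, 1)
          chain <- append(unname(deco), scaf, after = pos - 1L)
          res <- assembleChain(chain, mark = pos)
        } else {
          res <- assembleChain(unname(deco))
        }
        smis[i] <- res$smiles
        detailRows[[length(detailRows) + 1L]] <- data.frame(
          target = gene, compound_id = sprintf("%s_A%04d", gene, i),
          carries_scaffold = carries,
          scaffold_offset = res$scaffoldOffset,
          scaffold_length = res$scaffoldLength)
      }
      actives <- CompoundSet(sprintf("%s_A%04d", gene,
                                     seq_len(nActivesPerTarget)),
                             smis, label = 1L)
      # decoy pool: decoration-only chains, oversampled for exclusions
      nPool <- ceiling(decoyRatio * nActivesPerTarget * 1.5)
      poolSmis <- vapply(seq_len(nPool), function(i) {
        assembleChain(unname(sample(voc$decorations, sample(2:4, 1),
                                    replace = TRUE)))$smiles
      }, character(1))
      pool <- CompoundSet(sprintf("%s_P%05d", gene, seq_len(nPool)), poolSmis)
      subSeed <- sample.int(2147483646L, 2)
      decoys <- sampleDecoys(actives, pool, ratio = decoyRatio,
                             seed = subSeed[1])
      decoys@compoundId <- sprintf("%s_D%04d", gene, seq_along(decoys@smiles))
      ms <- ModelingSet(list(gene_symbol = gene, scaffold = scaf),
                        actives, decoys, decoyRatio = decoyRatio, seed = seed)
      ms <- splitTrainTest(ms, ratio = splitRatio, seed = subSeed[2])
      sets[[gene]] <- ms
      truthRows[[t]] <- data.frame(target = gene,
                                   scaffold_name = names(voc$scaffolds)[scafIdx[t]],
                                   scaffold = scaf)
    }
    list(sets = sets,
         truth = do.call(rbind, truthRows),
         activeDetails = do.call(rbind, detailRows))
  })
}

#' Persist / load a ModelingSet as a plain-text directory
#'
#' Writes `actives.smi` and `decoys.smi` (SMILES + id per line), `split.csv`
#' and a JSON `manifest.json` with target metadata, ratios and seed.
#'
#' @param ms a [ModelingSet-class].
#' @param dir directory to create/fill.
#' @return `dir` (for `writeModelingSet`) / a [ModelingSet-class] (for
#'   `readModelingSet`).
#' @export
writeModelingSet <- function(ms, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  writeLines(sprintf("%s %s", ms@actives@smiles, ms@actives@compoundId),
             file.path(dir, "actives.smi"))
  writeLines(sprintf("%s %s", ms@decoys@smiles, ms@decoys@compoundId),
             file.path(dir, "decoys.smi"))
  utils::write.csv(data.frame(compound_id = names(ms@split),
                              subset = unname(ms@split)),
                   file.path(dir, "split.csv"), row.names = FALSE,
                   quote = FALSE)
  jsonlite::write_json(list(target = ms@target, decoy_ratio = ms@decoyRatio,
                            seed = ms@seed,
                            n_actives = length(ms@actives),
                            n_decoys = length(ms@decoys)),
                       file.path(dir, "manifest.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' @rdname writeModelingSet
#' @export
readModelingSet <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  actives <- readCompounds(file.path(dir, "actives.smi"), format = "smi")
  decoys <- readCompounds(file.path(dir, "decoys.smi"), format = "smi")
  split <- utils::read.csv(file.path(dir, "split.csv"),
                           stringsAsFactors = FALSE)
  ms <- ModelingSet(as.list(man$target), actives, decoys,
                    decoyRatio = man$decoy_ratio, seed = man$seed)
  ms@split <- structure(split$subset, names = split$compound_id)[
    c(actives@compoundId, decoys@compoundId)]
  validObject(ms)
  ms
}
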