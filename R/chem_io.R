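#' Construct a CompoundSet
#'
#' @param compoundId character vector of unique compound identifiers.
#' @param smiles character vector of SMILES strings.
#' @param activity numeric activity values in nM (NA when unmeasured).
#' @param activityType character; `"Ki"`, `"IC50"`, `"EC50"` or `"none"`.
#' @param label integer; `+1` active, `-1` decoy, `NA` unlabeled.
#' @return a [CompoundSet-class] object.
#' @examples
#' cs <- CompoundSet(c("a", "b"), c("CCO", "c1ccccc1"))
#' length(cs)
#' @export
CompoundSet <- function(compoundId, smiles, activity = NA_real_,
                        activityType = "none", label = NA_integer_) {
  n <- length(compoundId)
  new("CompoundSet",
      compoundId   = as.character(compoundId),
      smiles       = as.character(smiles),
      activity     = rep_len(as.numeric(activity), n),
      activityType = rep_len(as.character(activityType), n),
      label        = rep_len(as.integer(label), n))
}

#' @rdname CompoundSet
#' @export
setMethod("compoundIds", "CompoundSet", function(x) x@compoundId)

#' @rdname CompoundSet
#' @export
setMethod("compoundSmiles", "CompoundSet", function(x) {
  structure(x@smiles, names = x@compoundId)
})

#' @rdname CompoundSet
#' @export
setMethod("activityValues", "CompoundSet", function(x) {
  structure(x@activity, names = x@compoundId)
})

#' @rdname CompoundSet
#' @export
setMethod("compoundLabels", "CompoundSet", function(x) {
  structure(x@label, names = x@compoundId)
})

#' @rdname CompoundSet
#' @export
setMethod("standardizationLog", "CompoundSet", function(x) x@stdLog)

#' @rdname CompoundSet
#' @export
setMethod("length", "CompoundSet", function(x) length(x@compoundId))

#' @rdname CompoundSet
#' @param i index vector
#' @param j,drop,... ignored
#' @export
setMethod("[", "CompoundSet", function(x, i, j, ..., drop = TRUE) {
  initialize(x,
             compoundId   = x@compoundId[i],
             smiles       = x@smiles[i],
             activity     = x@activity[i],
             activityType = x@activityType[i],
             label        = x@label[i])
})

setMethod("show", "CompoundSet", function(object) {
  n <- length(object)
  cat("CompoundSet with", n, "compounds\n")
  if (n) {
    lab <- object@label
    cat(sprintf("  actives (+1): %d | decoys (-1): %d | unlabeled: %d\n",
                sum(lab == 1L, na.rm = TRUE), sum(lab == -1L, na.rm = TRUE),
                sum(is.na(lab))))
    k <- min(n, 3L)
    for (i in seq_len(k))
      cat(sprintf("  %s  %s\n", object@compoundId[i], object@smiles[i]))
    if (n > k) cat("  ...\n")
  }
  if (nrow(object@stdLog))
    cat("  standardization log:", nrow(object@stdLog), "events\n")
  invisible(NULL)
})

#' @rdname CompoundSet
#' @param row.names,optional passed through to `data.frame`
#' @export
setMethod("as.data.frame", "CompoundSet",
  function(x, row.names = NULL, optional = FALSE, ...) {
    data.frame(compound_id = x@compoundId, smiles = x@smiles,
               activity_value = x@activity, activity_type = x@activityType,
               label = x@label, stringsAsFactors = FALSE)
  })

#' Canonicalize SMILES strings
#'
#' Converts SMILES to canonical form with OpenBabel (via ChemmineOB).
#' Canonicalization is idempotent; unparseable input yields `NA`.
#'
#' @param smiles character vector of SMILES.
#' @return character vector of canonical SMILES (NA where parsing failed).
#' @examples
#' canonicalSmiles(c("OCC", "CCO"))  # identical output
#' @export
canonicalSmiles <- function(smiles) {
  vapply(as.character(smiles), function(s) {
    if (is.na(s) || !nzchar(s)) return(NA_character_)
    out <- tryCatch(ChemmineOB::convertFormat("SMI", "CAN", source = s),
                    error = function(e) "")
    out <- sub("[\t\n ].*$", "", out)
    if (!nzchar(out)) NA_character_ else out
  }, character(1), USE.NAMES = FALSE)
}

# Pick the parent fragment of a (possibly multi-fragment) canonical SMILES:
# most heavy atoms, ties by molecular weight, then lexicographically.
# Fragments containing carbon are preferred over inorganic counter-ions.
largestOrganicFragment <- function(canSmi) {
  frags <- strsplit(canSmi, ".", fixed = TRUE)[[1]]
  if (length(frags) == 1L) return(frags)
  props <- lapply(frags, function(f) {
    sdf <- tryCatch(suppressWarnings(ChemmineR::smiles2sdf(f)),
                    error = function(e) NULL)
    if (is.null(sdf)) return(NULL)
    counts <- ChemmineR::atomcount(sdf)[[1]]
    mw <- tryCatch(ChemmineOB::prop_OB(
      ChemmineOB::forEachMol("SMILES", f, identity))$MW,
      error = function(e) NA_real_)
    list(heavy = sum(counts), hasC = "C" %in% names(counts), mw = mw %||% NA_real_)
  })
  ok <- !vapply(props, is.null, logical(1))
  frags <- frags[ok]; props <- props[ok]
  if (!length(frags)) return(NA_character_)
  hasC <- vapply(props, `[[`, logical(1), "hasC")
  if (any(hasC)) { frags <- frags[hasC]; props <- props[hasC] }
  heavy <- vapply(props, `[[`, numeric(1), "heavy")
  mw    <- vapply(props, `[[`, numeric(1), "mw")
  ord <- order(-heavy, -ifelse(is.na(mw), 0, mw), frags)
  frags[ord[1]]
}

#' Standardize a compound collection
#'
#' Applies the standard ligand preparation steps: parse and canonicalize every
#' structure, reduce salts/hydrates to the largest organic fragment, and
#' remove duplicate molecules (same canonical structure; stereochemistry-aware).
#' The first occurrence of each structure is kept and input order preserved.
#' Every drop or merge is recorded in the standardization log; unparseable
#' records are skipped and logged, never silently dropped.
#'
#' @param x a [CompoundSet-class].
#' @return a [CompoundSet-class] with canonical structures and a filled
#'   [standardizationLog()].
#' @examples
#' cs <- CompoundSet(c("a", "b", "c"), c("CCO", "OCC", "CCO.Cl"))
#' std <- standardizeCompounds(cs)
#' compoundSmiles(std)          # one record: duplicates and salt collapsed
#' standardizationLog(std)
#' @export
standardizeCompounds <- function(x) {
  stopifnot(is(x, "CompoundSet"))
  log <- list()
  note <- function(id, event, detail)
    log[[length(log) + 1L]] <<- data.frame(compound_id = id, event = event,
                                           detail = detail,
                                           stringsAsFactors = FALSE)
  n <- length(x)
  keep <- logical(n)
  canon <- character(n)
  for (i in seq_len(n)) {
    can <- canonicalSmiles(x@smiles[i])
    if (is.na(can)) {
      note(x@compoundId[i], "unparseable", x@smiles[i])
      next
    }
    if (grepl(".", can, fixed = TRUE)) {
      frag <- largestOrganicFragment(can)
      if (is.na(frag)) {
        note(x@compoundId[i], "unparseable", can)
        next
      }
      note(x@compoundId[i], "salt_stripped", sprintf("%s -> %s", can, frag))
      can <- canonicalSmiles(frag)
    }
    canon[i] <- can
    keep[i] <- TRUE
  }
  # deduplicate on canonical structure, first occurrence wins
  seen <- character(0)
  for (i in which(keep)) {
    if (canon[i] %in% seen) {
      first <- x@compoundId[keep & canon == canon[i]][1]
      note(x@compoundId[i], "duplicate_removed",
           sprintf("same structure as %s", first))
      keep[i] <- FALSE
    } else seen <- c(seen, canon[i])
  }
  out <- x[which(keep)]
  out@smiles <- canon[keep]
  out@stdLog <- if (length(log)) do.call(rbind, log) else x@stdLog[0, ]
  validObject(out)
  out
}

#' Label compounds by activity threshold
#'
#' Applies the activity rule used throughout: a compound is active (+1) iff
#' its Ki/IC50/EC50 is at or below `thresholdNM` (default 10 uM = 10000 nM,
#' inclusive). Compounds above the threshold are quarantined, not auto-labelled
#' as decoys: presumed inactives come from separate decoy sampling.
#'
#' @param x a [CompoundSet-class] whose compounds to label.
#' @param thresholdNM activity cutoff in nM (default 10000).
#' @return list with components `actives` (label +1), `inactive` (measured
#'   above threshold, quarantined) and `unmeasured` (no activity value).
#' @examples
#' cs <- CompoundSet(c("a", "b", "c"), c("CCO", "CCN", "CCC"),
#'                   activity = c(5000, 10000, 15000), activityType = "IC50")
#' lab <- labelByActivity(cs)
#' compoundIds(lab$actives)    # "a" (5 uM) and "b" (exactly 10 uM)
#' compoundIds(lab$inactive)   # "c" (15 uM): excluded, not a decoy
#' @export
labelByActivity <- function(x, thresholdNM = 10000) {
  stopifnot(is(x, "CompoundSet"))
  if (thresholdNM <= 0) stop("thresholdNM must be positive")
  act <- x@activity
  if (any(!is.na(act) & act <= 0))
    stop("activity values must be positive; found non-positive entries")
  isActive <- !is.na(act) & act <= thresholdNM
  isInact  <- !is.na(act) & act >  thresholdNM
  actives <- x[which(isActive)]
  actives@label <- rep(1L, length(actives))
  list(actives    = actives,
       inactive   = x[which(isInact)],
       unmeasured = x[which(is.na(act))])
}

#' Read compounds from CSV/TSV, SMILES or SDF files
#'
#' CSV/TSV files use columns `compound_id`, `smiles`, and optionally
#' `activity_value`, `activity_unit` (`nM` or `uM`; converted to nM at read
#' time) and `activity_type`. Plain SMILES files carry one molecule per line
#' with an optional whitespace-separated id. SDF files are read with
#' ChemmineR; activity fields are taken from equally named data-block
#' properties.
#'
#' @param path input file.
#' @param format `"auto"` (by extension), `"csv"`, `"tsv"`, `"smi"` or `"sdf"`.
#' @return a [CompoundSet-class] (raw; run [standardizeCompounds()] next).
#' @export
readCompounds <- function(path, format = c("auto", "csv", "tsv", "smi", "sdf")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, csv = "csv", tsv = "tsv", txt = "tsv",
                     smi = "smi", smiles = "smi", sdf = "sdf",
                     stop("cannot infer format from extension: ", ext))
  }
  if (format %in% c("csv", "tsv")) {
    df <- utils::read.table(path, header = TRUE,
                            sep = if (format == "csv") "," else "\t",
                            stringsAsFactors = FALSE, comment.char = "")
    if (!all(c("compound_id", "smiles") %in% names(df)))
      stop("need columns compound_id and smiles")
    act <- if ("activity_value" %in% names(df)) as.numeric(df$activity_value)
           else rep(NA_real_, nrow(df))
    if ("activity_unit" %in% names(df)) {
      unit <- tolower(df$activity_unit)
      isUM <- !is.na(unit) & unit %in% c("um", "µm", "μm")
      act[isUM] <- act[isUM] * 1000
      bad <- !is.na(unit) & nzchar(unit) & !isUM & unit != "nm"
      if (any(bad)) stop("unknown activity unit: ", unique(unit[bad])[1])
    }
    typ <- if ("activity_type" %in% names(df)) df$activity_type else "none"
    return(CompoundSet(df$compound_id, df$smiles, act, typ))
  }
  if (format == "smi") {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    parts <- strsplit(trimws(lines), "[ \t]+")
    smi <- vapply(parts, `[`, character(1), 1)
    ids <- vapply(seq_along(parts), function(i)
      if (length(parts[[i]]) > 1) parts[[i]][2] else sprintf("cmpd_%04d", i),
      character(1))
    return(CompoundSet(ids, smi))
  }
  # SDF
  sdf <- ChemmineR::read.SDFset(path)
  ChemmineR::cid(sdf) <- ChemmineR::makeUnique(ChemmineR::sdfid(sdf))
  smi <- as.character(ChemmineR::sdf2smiles(sdf))
  blocks <- ChemmineR::datablock(sdf)
  getProp <- function(b, key) if (key %in% names(b)) b[[key]] else NA
  act <- vapply(blocks, function(b)
    suppressWarnings(as.numeric(getProp(b, "activity_value"))), numeric(1))
  unit <- vapply(blocks, function(b)
    as.character(getProp(b, "activity_unit") %||% NA_character_), character(1))
  isUM <- !is.na(unit) & tolower(unit) %in% c("um", "µm", "μm")
  act[isUM] <- act[isUM] * 1000
  typ <- vapply(blocks, function(b) {
    v <- getProp(b, "activity_type")
    if (is.na(v[1])) "none" else as.character(v)
  }, character(1))
  CompoundSet(ChemmineR::cid(sdf), smi, act, typ)
}

#' Write a compound collection as canonical-SMILES CSV
#'
#' @param x a [CompoundSet-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeCompounds <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write the standardization log as line-oriented text
#'
#' @param x a standardized [CompoundSet-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeStandardizationLog <- function(x, path) {
  log <- standardizationLog(x)
  lines <- sprintf("%s\t%s\t%s", log$compound_id, log$event, log$detail)
  writeLines(lines, path)
  invisible(path)
}
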