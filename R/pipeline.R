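# Command-line pipeline: thin subcommand layer over the package functions.
# Subcommands: build-dataset, train, evaluate, predict, network.
# Every stochastic step receives an explicit seed so reruns are
# byte-identical; a run log records versions, seeds and counts (no
# timestamps, deliberately, to keep artifacts reproducible).

cliUsage <- function() {
  paste(
    "usage: mtqsar <subcommand> [--flag value ...]",
    "",
    "subcommands:",
    "  build-dataset  --out-dir D [--seed N] [--n-targets K] [--n-actives N]",
    "                 [--signal S] [--decoy-ratio R] [--split-ratio R]",
    "                 [--actives FILE --pool FILE --gene SYMBOL",
    "                  --threshold-nM T [--property-matched]]",
    "  train          --out-dir D [--nbits N] [--max-depth D] [--min-node M]",
    "  evaluate       --out-dir D [--folds K] [--seed N] [--nbits N]",
    "                 [--max-depth D] [--min-node M]",
    "  predict        --out-dir D --input FILE",
    "  network        --out-dir D",
    sep = "\n")
}

parseFlags <- function(args) {
  flags <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--"))
      stop("unexpected argument: ", a, call. = FALSE)
    key <- substring(a, 3)
    if (key %in% c("property-matched")) {        # boolean flags
      flags[[key]] <- TRUE
      i <- i + 1L
    } else {
      if (i == length(args))
        stop("flag --", key, " needs a value", call. = FALSE)
      flags[[key]] <- args[i + 1L]
      i <- i + 2L
    }
  }
  flags
}

flagNum <- function(flags, key, default) {
  if (is.null(flags[[key]])) return(default)
  v <- suppressWarnings(as.numeric(flags[[key]]))
  if (is.na(v)) stop("flag --", key, " must be numeric", call. = FALSE)
  v
}

logRun <- function(outDir, lines) {
  path <- file.path(outDir, "run.log")
  con <- file(path, open = "a")
  on.exit(close(con))
  writeLines(lines, con)
}

cmdBuildDataset <- function(flags) {
  outDir <- flags[["out-dir"]] %||% stop("--out-dir is required", call. = FALSE)
  dir.create(file.path(outDir, "datasets"), recursive = TRUE,
             showWarnings = FALSE)
  seed <- as.integer(flagNum(flags, "seed", 2017))
  decoyRatio <- flagNum(flags, "decoy-ratio", 3)
  splitRatio <- flagNum(flags, "split-ratio", 3)
  if (!is.null(flags[["actives"]])) {
    # real-data mode: standardize + label the actives, sample decoys
    gene <- flags[["gene"]] %||% stop("--gene is required with --actives",
                                      call. = FALSE)
    raw <- standardizeCompounds(readCompounds(flags[["actives"]]))
    lab <- labelByActivity(raw, thresholdNM = flagNum(flags, "threshold-nM",
                                                      10000))
    pool <- standardizeCompounds(readCompounds(
      flags[["pool"]] %||% stop("--pool is required with --actives",
                                call. = FALSE)))
    decoys <- sampleDecoys(lab$actives, pool, ratio = decoyRatio, seed = seed,
                           propertyMatched = isTRUE(flags[["property-matched"]]))
    ms <- ModelingSet(list(gene_symbol = gene), lab$actives, decoys,
                      decoyRatio = decoyRatio, seed = seed)
    ms <- splitTrainTest(ms, ratio = splitRatio, seed = seed + 1L)
    sets <- stats::setNames(list(ms), gene)
    genes <- gene
  } else {
    bench <- makeSyntheticBenchmark(
      nTargets = as.integer(flagNum(flags, "n-targets", 2)),
      nActivesPerTarget = as.integer(flagNum(flags, "n-actives", 100)),
      decoyRatio = decoyRatio,
      signalStrength = flagNum(flags, "signal", 0.9),
      seed = seed, splitRatio = splitRatio)
    sets <- bench$sets
    genes <- names(sets)
    utils::write.csv(bench$truth, file.path(outDir, "scaffold_truth.csv"),
                     row.names = FALSE, quote = FALSE)
  }
  for (gene in genes)
    writeModelingSet(sets[[gene]], file.path(outDir, "datasets", gene))
  targets <- data.frame(
    gene_symbol = genes,
    subfamily = mechanismClasses[(seq_along(genes) - 1L) %%
                                   length(mechanismClasses) + 1L])
  utils::write.csv(targets, file.path(outDir, "targets.csv"),
                   row.names = FALSE, quote = FALSE)
  logRun(outDir, c(
    sprintf("build-dataset mtqsar=%s seed=%d decoy_ratio=%g split_ratio=%g",
            as.character(utils::packageVersion("mtqsar")), seed, decoyRatio,
            splitRatio),
    sprintf("  target=%s n_actives=%d n_decoys=%d", genes,
            vapply(sets, function(s) length(msActives(s)), integer(1)),
            vapply(sets, function(s) length(msDecoys(s)), integer(1)))))
  0L
}

datasetDirs <- function(outDir) {
  root <- file.path(outDir, "datasets")
  if (!dir.exists(root))
    stop("no datasets under ", outDir, "; run build-dataset first",
         call. = FALSE)
  dirs <- list.dirs(root, recursive = FALSE)
  if (!length(dirs)) stop("no datasets under ", root, call. = FALSE)
  sort(dirs)
}

cmdTrain <- function(flags) {
  outDir <- flags[["out-dir"]] %||% stop("--out-dir is required", call. = FALSE)
  nbits <- as.integer(flagNum(flags, "nbits", 2048))
  maxDepth <- as.integer(flagNum(flags, "max-depth", 20))
  minNode <- as.integer(flagNum(flags, "min-node", 10))
  for (d in datasetDirs(outDir)) {
    ms <- readModelingSet(d)
    gene <- msTarget(ms)$gene_symbol
    quartet <- trainClassifierQuartet(ms, nbits = nbits, maxDepth = maxDepth,
                                      minSamplesPerNode = minNode)
    mdir <- file.path(outDir, "models", gene)
    dir.create(mdir, recursive = TRUE, showWarnings = FALSE)
    for (nm in names(quartet))
      saveModel(quartet[[nm]], file.path(mdir, paste0(nm, ".json")))
    logRun(outDir, sprintf("train target=%s n_train=%d nbits=%d", gene,
                           sum(msSplit(ms) == "train"), nbits))
  }
  0L
}

evalTrainers <- function(maxDepth, minNode) {
  list(nb = trainNaiveBayes,
       rp = function(fps, labels)
         trainRecursivePartitioning(fps, labels, maxDepth = maxDepth,
                                    minSamplesPerNode = minNode))
}

cmdEvaluate <- function(flags) {
  outDir <- flags[["out-dir"]] %||% stop("--out-dir is required", call. = FALSE)
  folds <- as.integer(flagNum(flags, "folds", 5))
  seed <- as.integer(flagNum(flags, "seed", 2017))
  nbits <- as.integer(flagNum(flags, "nbits", 2048))
  trainers <- evalTrainers(as.integer(flagNum(flags, "max-depth", 20)),
                           as.integer(flagNum(flags, "min-node", 10)))
  rows <- list()
  for (d in datasetDirs(outDir)) {
    ms <- readModelingSet(d)
    gene <- msTarget(ms)$gene_symbol
    train <- msCompounds(ms, "train")
    test <- msCompounds(ms, "test")
    for (scheme in c("ecfp6", "maccs")) {
      schemeName <- if (scheme == "ecfp6") "ECFP6" else "MACCS166"
      fpsTrain <- computeFingerprints(train, schemeName, nbits = nbits)
      fpsTest <- computeFingerprints(test, schemeName, nbits = nbits)
      for (alg in c("nb", "rp")) {
        cv <- kFoldCV(fpsTrain, train@label, trainers[[alg]], k = folds,
                      seed = seed)
        model <- trainers[[alg]](fpsTrain, train@label)
        tm <- metricsFromScores(test@label, modelPredict(model, fpsTest),
                                modelScores(model, fpsTest))
        for (kind in c("cv", "test")) {
          m <- if (kind == "cv") cv$pooled else tm
          rows[[length(rows) + 1L]] <- data.frame(
            target = gene, algorithm = alg, scheme = scheme,
            eval_kind = kind, SE = m$SE, SP = m$SP, Q = m$Q, MCC = m$MCC,
            AUC = m$AUC, stringsAsFactors = FALSE)
        }
      }
    }
  }
  tab <- do.call(rbind, rows)
  writeMetricsTable(tab, file.path(outDir, "metrics.csv"))
  logRun(outDir, sprintf("evaluate folds=%d seed=%d rows=%d", folds, seed,
                         nrow(tab)))
  0L
}

cmdPredict <- function(flags) {
  outDir <- flags[["out-dir"]] %||% stop("--out-dir is required", call. = FALSE)
  input <- flags[["input"]] %||% stop("--input is required", call. = FALSE)
  mroot <- file.path(outDir, "models")
  if (!dir.exists(mroot))
    stop("no models under ", outDir, "; run train first", call. = FALSE)
  library_ <- list()
  for (mdir in sort(list.dirs(mroot, recursive = FALSE))) {
    gene <- basename(mdir)
    files <- file.path(mdir, paste0(VOTE_ORDER, ".json"))
    present <- file.exists(files)
    if (!all(present))
      stop("incomplete model quartet for target ", gene, ": missing ",
           paste(VOTE_ORDER[!present], collapse = ", "), call. = FALSE)
    library_[[gene]] <- stats::setNames(lapply(files, loadModel), VOTE_ORDER)
  }
  compounds <- standardizeCompounds(readCompounds(input))
  profile <- predictProfile(compounds, library_)
  writePredictions(profile, file.path(outDir, "predictions.csv"))
  logRun(outDir, sprintf("predict input=%s n_compounds=%d n_targets=%d",
                         basename(input), length(compounds),
                         length(library_)))
  0L
}

cmdNetwork <- function(flags) {
  outDir <- flags[["out-dir"]] %||% stop("--out-dir is required", call. = FALSE)
  predPath <- file.path(outDir, "predictions.csv")
  if (!file.exists(predPath))
    stop("no predictions.csv under ", outDir, "; run predict first",
         call. = FALSE)
  calls <- utils::read.csv(predPath, stringsAsFactors = FALSE)
  targets <- utils::read.csv(file.path(outDir, "targets.csv"),
                             stringsAsFactors = FALSE)
  net <- buildNetwork(calls, targets)
  exportSIF(net, file.path(outDir, "network.sif"))
  exportGraphML(net, file.path(outDir, "network.graphml"))
  st <- networkStats(net)
  jsonlite::write_json(
    list(n_compounds = length(net@compounds), n_targets = length(net@targets),
         n_edges = st$nEdges,
         mean_targets_per_compound = st$meanTargetsPerCompound,
         mean_compounds_per_target = st$meanCompoundsPerTarget),
    file.path(outDir, "network_stats.json"), auto_unbox = TRUE, digits = NA)
  logRun(outDir, sprintf("network edges=%d compounds=%d targets=%d",
                         st$nEdges, length(net@compounds),
                         length(net@targets)))
  0L
}

#' Command-line entry point
#'
#' Dispatches the pipeline subcommands (`build-dataset`, `train`,
#' `evaluate`, `predict`, `network`). Installed alongside the package as the
#' executable script `exec/mtqsar.R`. Usage errors return status 2, runtime
#' failures status 1; artifacts are reproducible byte-for-byte under a fixed
#' `--seed`.
#'
#' @param args character vector of command-line arguments (e.g.
#'   `commandArgs(trailingOnly = TRUE)`).
#' @return integer exit status, invisibly.
#' @export
mtqsarCLI <- function(args) {
  if (!length(args) || args[1] %in% c("-h", "--help", "help")) {
    cat(cliUsage(), "\n")
    return(invisible(if (length(args)) 0L else 2L))
  }
  sub <- args[1]
  handler <- switch(sub,
                    "build-dataset" = cmdBuildDataset,
                    "train" = cmdTrain,
                    "evaluate" = cmdEvaluate,
                    "predict" = cmdPredict,
                    "network" = cmdNetwork,
                    NULL)
  if (is.null(handler)) {
    message("unknown subcommand: ", sub, "\n", cliUsage())
    return(invisible(2L))
  }
  flags <- tryCatch(parseFlags(args[-1]), error = function(e) {
    message("usage error: ", conditionMessage(e))
    NULL
  })
  if (is.null(flags)) return(invisible(2L))
  status <- tryCatch(handler(flags), error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}
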