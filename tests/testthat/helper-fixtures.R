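# Shared fixtures, built in code. The standard synthetic benchmark (100
# actives, 3:1 decoys, signal 0.9) is expensive enough to build once per
# session and reuse across test files.

fpSet <- function(features, nbits = 16L, scheme = "ECFP6",
                  ids = sprintf("c%02d", seq_along(features))) {
  new("FingerprintSet", scheme = scheme, nbits = as.integer(nbits),
      features = lapply(features, as.integer), ids = ids)
}

.benchCache <- new.env(parent = emptyenv())

standardBenchmark <- function() {
  if (is.null(.benchCache$bench)) {
    .benchCache$bench <- makeSyntheticBenchmark(
      nTargets = 1, nActivesPerTarget = 100, decoyRatio = 3,
      signalStrength = 0.9, seed = 2017)
  }
  .benchCache$bench
}

standardQuartet <- function() {
  if (is.null(.benchCache$quartet)) {
    .benchCache$quartet <- trainClassifierQuartet(standardBenchmark()$sets[[1]])
  }
  .benchCache$quartet
}

# random sparse binary fingerprints for property-style checks
randomFeatureSets <- function(n, nbits = 64L, lambda = 8) {
  lapply(seq_len(n), function(i) {
    k <- stats::rpois(1, lambda)
    sort(sample.int(nbits, min(k, nbits)) - 1L)
  })
}
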