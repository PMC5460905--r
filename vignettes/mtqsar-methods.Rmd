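---
title: "Multi-target QSAR modelling of chemical-protein interactions: methods"
author: "mtqsar package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-target QSAR modelling of chemical-protein interactions: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mtqsar)
```

## The modelling problem

Ligand-based target prediction asks: given only a compound's structure,
which protein targets is it likely to modulate? For a multifactorial disease
such as Alzheimer's, where single-target drugs have shown limited benefit,
the question becomes multi-target: a candidate molecule is screened against
a whole library of disease-relevant targets at once, and compounds hitting
several targets (multi-target-directed ligands) are of particular interest.

`mtqsar` implements the multi-target QSAR (mt-QSAR) strategy: the
multi-label problem is decomposed into one binary classifier per target.
Each per-target classifier separates *actives* — compounds with a measured
Ki, IC50 or EC50 at or below 10 µM against that target — from presumed
inactive *decoys* drawn from a background library at a fixed 3:1
decoy:active ratio. For every target, four classifiers are trained (two
learning algorithms × two fingerprint types), and their votes are combined
into a consensus interaction call.

## Compound standardization

Raw ligand collections contain duplicates, salts and occasional unparseable
records. `standardizeCompounds()` applies the standard preparation steps in
a fixed order: canonicalize each SMILES (OpenBabel canonical form, which is
idempotent), reduce multi-fragment structures to the parent — the fragment
with the most heavy atoms, preferring fragments containing carbon, ties
broken by molecular weight and then lexicographically — and drop duplicate
canonical structures, keeping the first occurrence. Every removal or merge
is recorded in a standardization log; unparseable records are logged, never
silently dropped. Deduplication is performed on the stereochemistry-aware
canonical form: two stereoisomers remain distinct records. Hydrate/solvent
removal is subsumed by parent-fragment selection. Tautomer enumeration and
protonation-state modelling are out of scope.

Activity labelling is deliberately asymmetric: compounds at or below the
10 µM cutoff (inclusive) become actives (+1), but compounds measured
*above* the cutoff are quarantined rather than auto-labelled as decoys —
weak binders are not a random background sample, and the negative class is
instead drawn from a decoy pool. Activities are stored in nM; per-row
`nM`/`µM` units are converted at read time.

## Fingerprints

Two binary fingerprint families describe each molecule:

* **Circular (ECFP-style)** fingerprints, diameter 2 (`ECFP2`, radius 1)
  and diameter 6 (`ECFP6`, radius 3). Per-atom initial invariants (atomic
  number, heavy-atom degree, implicit hydrogen count, ring membership) are
  iteratively combined with sorted `(bond order, neighbour identifier)`
  pairs, Morgan-style; every identifier is produced by a fixed 31-bit
  integer hash, so feature identifiers are stable across runs and
  platforms — never process-randomized. Features are folded to 2048 bits by
  default; the classifiers can alternatively consume the unfolded sparse
  identifiers (`folded = FALSE`). Molecules are processed on the kekulized
  bond graph, so alternative aromatic spellings of one molecule should be
  canonicalized first (the standardization step guarantees this). Formal
  charges are not part of the atom invariants; for the neutral organic
  chemistry the package targets this loses no discrimination, but strongly
  charged species will alias onto their neutral analogues. The
  implementation keeps the mapping from each feature to its generating atom
  environment (`ecfpEnvironments()`), which is what lets a top-ranked naive
  Bayes feature be traced back to a substructure.
* **MACCS166** structural keys, the 166-pattern public-key dictionary,
  computed with OpenBabel. Indices are stored 0-based (key number − 1).

Chemical diversity of a data set is summarized by the mean pairwise
Tanimoto similarity on ECFP2 (`diversityIndex()`): smaller is more diverse.
The mean-over-all-unordered-pairs aggregation is a documented choice — a
mean nearest-neighbour similarity is another common convention, and single
published "Tanimoto index" columns rarely say which they used. Two empty
fingerprints are defined to have similarity 1.

## Classifiers

### Laplacian-corrected naive Bayes

For training compounds with prior active fraction $P = n_+ / n$, a feature
$f$ seen in $T_f$ compounds of which $A_f$ are active gets the log-weight

$$W_f = \ln \frac{A_f + 1}{T_f \, P + 1},$$

the Laplacian-corrected relative frequency estimate standard in
fingerprint-Bayesian screening: the correction adds virtual samples at the
base rate, so rare features cannot produce infinite weights, a feature
occurring at exactly the base rate gets weight 0 (to within rounding), and
weights are finite for every observed feature. A compound's score is the
sum of the weights of its on-features; features unseen in training
contribute 0, and the empty fingerprint scores 0. The decision threshold
defaults to 0 (score above threshold ⇒ active); `calibrateThreshold()`
optionally picks the MCC-maximizing cutoff on training data instead, since
the best operating point is data-dependent. Scores are additive over
feature-set unions, which the test suite checks as an invariant.

### Recursive partitioning

A binary decision tree splits on presence/absence of single fingerprint
features, grown greedily by Gini impurity decrease with an exhaustive
search over the features observed at each node. Ties in impurity decrease
are broken by the smallest feature index, making training fully
deterministic. Splits with zero impurity decrease are permitted (provided
the feature actually divides the node), which is what lets XOR-structured
labels over two features be resolved at depth 2; runaway splitting is
bounded by the depth cap and the node-size floor. Splitting stops at pure
nodes, at `maxDepth`, or when a child would fall below `minSamplesPerNode`.
Defaults are `maxDepth = 20` and `minSamplesPerNode = 10`; both are exposed
because published parameter reports for this model family are often
ambiguous, and the right values depend on training-set size. Leaves predict
the majority class (ties to the decoy class, the conservative choice for
screening); the leaf active fraction serves as a ranking score for ROC
analysis.

Both model types serialize to versioned JSON
(`saveModel()`/`loadModel()`); numeric parameters are written with 17
significant digits so reloaded models score bit-identically. Corrupted or
mis-versioned files raise errors rather than yielding partial models.

## Evaluation

Classification quality uses the four confusion counts and the standard
derived metrics: sensitivity SE = TP/(TP+FN), specificity SP = TN/(TN+FP),
overall accuracy Q, and the Matthews correlation coefficient. Any metric
with a zero denominator is reported as 0 and flagged, rather than NaN.

ROC AUC is computed by pair counting (the Mann–Whitney statistic: the
fraction of active/decoy pairs ranked correctly, ties counted ½). An
independent implementation by explicit threshold sweep and trapezoidal
integration (`aucTrapezoid()`) is maintained alongside it, and the test
suite checks their equality on a thousand random score sets, additionally
cross-checking against the pROC package.

`kFoldCV()` performs stratified k-fold cross-validation (default k = 5,
i.e. 80%/20% train/validation): per-class fold sizes differ by at most one,
every compound is validated exactly once, and fold assignment is
reproducible from the seed. Reported CV metrics are **pooled** over the
concatenated out-of-fold predictions rather than averaged across folds —
averaging ratios with different denominators drifts, and pooling keeps the
AUC well-defined; published work frequently does not state which convention
it used, so ours is documented here.

`aggregateMetricTable()` summarizes a metric over a model library:
five-number summary with quartiles by inclusive linear interpolation
(R's default quantile type 7), mean, and the count of values *strictly*
above a cutoff. The package bundles a published 104-classifier benchmark
(26 preclinical Alzheimer's-disease targets × 2 fingerprints × 2
algorithms; `benchmarkTable()`) whose printed aggregate statistics —
mean cross-validation MCC 0.887, mean test MCC 0.724, and the rest — are
recomputed exactly by these functions in `scripts/acceptance.R`. One known
inconsistency in the source tables: the worst target's four test MCC values
average 0.425, while the accompanying narrative quotes 0.501; the package
reproduces the table-derived value.

## Data sets and the synthetic benchmark

`sampleDecoys()` draws decoys uniformly without replacement from a
background pool after excluding any structure canonically identical to an
active, erroring (with the shortfall) if the pool is too small. An optional
property-matched mode stratifies sampling over the actives'
molecular-weight deciles, in the spirit of DUD-style decoy selection; both
modes are provided because published decoy sets vary in whether they
property-match. `splitTrainTest()` assigns a stratified 3:1 train/test
split per class, rounding toward the training side.

`makeSyntheticBenchmark()` generates fully synthetic per-target modelling
sets, so the entire pipeline is testable without licensed compound
libraries. The generator's defaults are the study conditions used
throughout: 100 actives per target, 3:1 decoys, 3:1 train/test split,
signal strength 0.9. Its construction:

* A built-in vocabulary of 38 fragments (12 distinctive fused-ring
  scaffolds + 26 common decorations), each a valid SMILES whose first and
  last atoms have free valence, so fragment chains concatenate into valid
  molecules (each junction is a single bond). All fragments and their
  random concatenations are validated by parsing in the test suite.
* Each target owns a private scaffold. An active is a chain of 2–4
  decorations drawn from a target-specific 10-fragment palette, carrying
  the scaffold with probability `signalStrength` at a random position.
  The palette emulates a congeneric series: real per-target actives share
  enriched substructures beyond a single core, and without it a
  scaffold-free active would be statistically indistinguishable from a
  decoy, making performance at signal strength 0.9 a knife-edge quantity.
* Decoys are chains over the full decoration vocabulary, passed through
  `sampleDecoys()`.
* Ground truth (scaffold per target, and each active's scaffold placement
  as heavy-atom offsets in SMILES order) is returned, enabling the
  parameter-recovery check: the top-weighted NB feature maps back, via
  `ecfpEnvironments()`, into the planted scaffold's atoms.

What the generator does *not* emulate: real activity cliffs, assay noise,
property-biased decoys, stereochemistry, charged species, and the scale of
real corpora (tens of thousands of ligands). Passing the synthetic
recovery tests therefore demonstrates that the machinery is correct and
sensitive to planted signal — not that real-data performance will match the
bundled benchmark tables.

Problem sizes for the recovery checks were chosen to keep the full suite
comfortably fast on a laptop: the headline benchmark uses one target with
100 actives/300 decoys; the signal-monotonicity sweep uses 40 actives per
set over five signal levels × ten seeds and measures pooled 5-fold CV AUC,
which is far less noisy than a 25-active test split at equal cost.

## Consensus calls and networks

A compound–target pair is called an interaction when **at least 2 of the 4**
per-target classifiers (NB_ECFP6, NB_MACCS, RP_ECFP6, RP_MACCS) vote
active. Of the 16 possible vote vectors, exactly 11 are positive
(C(4,2)+C(4,3)+C(4,4)), and the rule is monotone: flipping any single vote
to active never withdraws an interaction. Votes are unweighted — no
score-weighted variant is provided — and a missing classifier is an error,
never imputed. The vote order is fixed purely for stable serialization.

Positive calls build a bipartite compound–target network
(`buildNetwork()`), with annotation edges from targets to their mechanism
classes (a fixed seven-class vocabulary covering neurotransmission, tau
pathology, amyloid-β, intracellular signalling, inflammation, mitochondrial
and metabolic dysfunction; a target may belong to several). Mechanism nodes
are annotation-only: degree statistics (`networkStats()`) count
compound–target edges exclusively, which is the only convention under which
"mean targets per compound × compounds = edges = mean compounds per target
× targets" holds. Hub rankings break ties lexicographically. Exports (SIF
and GraphML) are written in sorted order so repeated runs are
byte-identical.

## Pipeline determinism

The command-line layer (`mtqsarCLI()`, installed as `exec/mtqsar.R`) wires
the stages together: `build-dataset`, `train`, `evaluate`, `predict`,
`network`. Every stochastic operation receives an explicit seed (default
2017, logged); RNG use is confined to `withSeed()` scopes so library code
never perturbs the caller's RNG state, and two runs with identical flags
produce byte-identical metrics tables and network exports. The run log
records package version, seeds and counts — and deliberately no
timestamps.

## Known limitations

* Circular fingerprints use kekulized bond orders; equivalence across
  aromatic spellings relies on prior canonicalization.
* Formal charge is not an atom invariant.
* No applicability-domain scoring: a consensus call for a compound far
  outside a model's training chemistry is extrapolation, and the bundled
  benchmark's weakest target (trained on only 60 actives) illustrates how
  narrow training domains degrade external performance.
* The recursive-partitioning trainer is exact but exhaustive; with
  unfolded sparse features on large corpora, folding to 2048 bits first is
  strongly advised.
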