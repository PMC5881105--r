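---
title: "Methods: sequence-derived features, forest-based feature selection and model tuning in aipkit"
author: "aipkit authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sequence-derived features, forest-based feature selection and model tuning in aipkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aipkit)
```

# The problem

Anti-inflammatory peptides (AIPs) induce anti-inflammatory cytokines
(IL-10, IL-4, IL-13, IL-22, TGF-β, IFN-α/β) in T-cell assays, and
candidate screening by machine learning is far cheaper than assaying
every peptide. `aipkit` implements the full methodology of a
sequence-only AIP classifier: fixed-length feature encodings of short
peptides (typically 5–30 residues), a random-forest importance-based
feature selection protocol, repeated cross-validated hyperparameter
tuning across four classifier families, and a threshold/ROC evaluation
suite. Because the original curated immunology datasets are external
resources, the package ships a seeded synthetic generator that emulates
their published compositional structure, so the entire pipeline is
exercisable and testable end-to-end.

# Feature encodings

All encoders consume validated sequences over the 20-letter canonical
alphabet (length ≥ 2, so dipeptides exist) and are deterministic.

**AAC** (20 values) is the residue composition, `count(i)/L`.

**DPC** (400 values) counts the `L − 1` overlapping ordered dipeptides.
The defining text normalizes "against 400 possible dipeptides"; we read
the denominator as the number of dipeptides *in the sequence* (`L − 1`),
the standard convention under which the vector sums to 1. Dividing by
the constant 400 instead would rescale every feature by the same
sequence-dependent factor `(L − 1)/400`; it is retained as the
`denominator = "constant"` option but is not the default.

**AAI** (20 values). Eight high-quality AAindex scales (BLAM930101,
BIOV880101, MAXF760101, TSAJ990101, NAKH920108, CEDJ970104, LIFS790101,
MIYS990104) are loaded from the `seqinr` distribution of the AAindex
database, min–max normalized over the 20 residues — the source
methodology does not state its normalization, and without one the
large-magnitude scales (e.g. residue volumes) would dominate the
average — then averaged into one profile `avg(i)`. For a variable-length
peptide we define `AAI(i) = AAC(i) × avg(i)`, which is 20-dimensional
and length-independent.

**CTD** (147 values). For seven physicochemical attributes
(hydrophobicity, normalized van der Waals volume, polarity,
polarizability, charge, secondary structure, solvent accessibility) the
residues are partitioned into three groups. The attribute tables are not
enumerated in the source methodology beyond the hydrophobicity example,
so we bundle the canonical three-group partitions of the
protein-folding-class descriptor literature (as propagated by
PROFEAT/iFeature). Per attribute: composition C (3 values, percent,
summing to 100), transition T (3 values, percent of adjacent pairs
crossing each unordered group pair), distribution D (per group, the
positions as percent of `L` of the first, 25 %, 50 %, 75 % and 100 %
occurrence). Occurrence indices use `ceiling(fraction × groupCount)`
with a minimum of 1 — off-by-one conventions differ between published
implementations, so ours is stated explicitly; an absent group
contributes five zeros.

**PCP** (9 values): hydrophobic, hydrophilic, neutral, positively and
negatively charged residue fractions, the turn-forming fraction
`(N+G+P+S)/n`, absolute charge per residue, molecular weight per
residue, and the aliphatic index `(A + 2.9V + 3.9I + 3.9L)/n`. Two
interpretation choices: the absolute-charge formula is unreadable in the
source (a figure placeholder), so we adopt
`|count(K)+count(R) − count(D) − count(E)|/n`, excluding histidine from
the arithmetic (it appears only in the positively-charged *fraction*
set); and molecular weight is divided by `n` (average residue masses
plus one water) so the feature does not trivially encode length.

The hybrid encoding concatenates any subset of the five blocks in the
fixed order AAC, AAI, DPC, CTD, PCP (full length
20 + 20 + 400 + 147 + 9 = 596).

# Feature selection

`estimateFIS()` estimates feature importance scores (FIS) by 5-fold
cross-validation: on each training fold it grows a forest whose
per-tree split-candidate count (`mtry`) is "chosen randomly from 1 to
50". Standard forest implementations fix `mtry` per forest, so the
protocol is realized by partitioning the trees (10,000 by default) into
equal sub-forests, one per `mtry` value — equivalent in expectation to a
per-tree draw. Gini importances are tree-weighted within a fold,
normalized per fold, averaged unweighted across folds and renormalized
to sum to 1. Whether the original protocol also averaged over the 10 CV
repetitions is unstated; the default is folds-only with a `repeats`
argument.

`generateFeatureSets()` first drops features with FIS below a floor
(default 0.0005), then emits one candidate set per cutoff in the sweep
0.0005–0.0039, step 0.0001 — 35 sets, nested by construction. The sweep
grid is generated by integer stepping so floating-point accumulation can
never change the set count. (The companion remark in the source that
"~36 % of the features (FIS ≥ 0.003) contributed significantly" mixes
thresholds inconsistently with this sweep; the sweep is the operative
protocol.)

# Model training and tuning

Four families are supported: random forest (RF) and extremely randomized
trees (ERT) via `ranger` (ERT = whole-sample training, `replace =
FALSE`, `sample.fraction = 1`, with randomized split points,
`splitrule = "extratrees"`), RBF-kernel SVM via `e1071` with Platt-style
probability calibration fitted within training folds, and k-NN via
`class` with the positive-neighbour fraction as probability.

The forest grid is `ntree` 50–990 step 20 **plus 1000** (the printed
range "50 to 1,000, step 20" does not land on 1000, so it is appended
explicitly), `mtry` 1–7 and `nsplit` 2–10, where `nsplit` — the minimum
samples to split an internal node — maps to `ranger`'s minimal node
size. SVM and k-NN grids are unspecified in the source ("same
procedures" as earlier work); defaults are `cost` `2^(-5..15)`, `gamma`
`2^(-15..3)` (×4 steps) and odd `k` 1–31, all configurable.

`gridSearch()` evaluates every grid point by mean out-of-fold AUC under
a repeated stratified CV plan; ties go to the smaller parameters
(`ntree`, then `mtry`, then `nsplit`). `consensusParams()` takes the
element-wise median across the per-repeat winners and snaps it to the
nearest grid point (ties toward the smaller value). Class imbalance is
handled only through the probability cutoff — never by resampling:
`tuneCutoff()` scans 0.01–0.99 (step 0.01) for the cutoff maximizing the
MCC of thresholded out-of-fold predictions. The metric the original
cutoff search optimized is unstated; MCC is chosen because it is the
headline threshold-dependent metric and is the one sensitive to the
imbalance that motivates a non-0.5 cutoff. Ties prefer the cutoff
closest to 0.5, then the smaller; calls are positive at probability
**≥** cutoff.

`runPipeline()` chains the stages (encode → FIS → sweep → per-set grid
search → select the set with highest mean AUC, ties to the larger set →
consensus parameters → final fit → cutoff tuning) and emits a per-set
AUC sweep report. Whether the original grid search was nested within
the feature-set sweep or run once on the full matrix is not fully
specified; per-set search is the default here. Model bundles embed the
selected feature names and an encoder version tag, and prediction
refuses to run on a version mismatch — silent feature misalignment being
the main failure mode of serialized sequence models.

# Evaluation

`thresholdMetrics()` implements sensitivity `TP/PS`, specificity
`TN/NS`, accuracy and MCC. The printed MCC equation in the source
methodology is typographically mangled (the radical is missing), so the
standard product-moment formula is the implementation and the
reconstructed "intuitive" form (`mccChou()`) is kept as an independent
cross-check; the two agree to 1e-12 over randomized confusion tables in
the test suite. AUC uses the rank (Mann–Whitney) formulation with ties
counting ½, which equals the trapezoidal area under the step ROC curve;
both identities are asserted against brute-force oracles.
`compareAUC()` applies a two-tailed Welch t-test to per-repeat AUC
samples from repeated CV — the inputs of the original test are not fully
specified, and a correlated-ROC test may have been intended; the Welch
form on per-repeat AUCs is the documented default.

# Enrichment analysis

`compositionEnrichment()` compares per-peptide AAC or DPC values between
classes with two-sided Welch t-tests — per-peptide compositions, not
pooled counts, are the test units. No multiple-testing correction is
applied by default (mirroring the raw `P ≤ 0.05` convention of the
field); Benjamini–Hochberg is available via `adjust = "BH"`. Items with
zero variance in both classes get `p = NA` (flagged `no_variance`) when
the means agree and `p = 0` when they differ. `positionalEnrichment()`
tests per-position residue indicators over the first `n` positions from
either terminus; C-terminal positions are indexed 1..n from the last
residue inward (the source never defines its C-terminal coordinate
convention, so ours is stated). Under a null generator the significant
fraction calibrates to α within binomial noise, which the test suite
checks by simulation.

# Redundancy reduction

`reduceRedundancy()` is a deliberate stand-in, not a CD-HIT
reproduction: records are visited longest-first (ties by id) and kept
only if their identity to every kept record is below the threshold
(default 0.8). Identity is the match count of a global alignment with
unit match score and free gaps/mismatches — equivalently the longest
common subsequence — normalized by the shorter length, the convention of
the clustering tools it stands in for. The procedure is deterministic
and idempotent, and the test suite verifies the all-pairs sub-threshold
property exhaustively on fixtures.

# The synthetic generator

`generatePeptides()` emulates the published compositional structure of
the AIP/non-AIP classes: the positive class up-weights Leu, Lys and Arg
twofold, the negative class up-weights Asp, Gly, Val, Tyr and Pro
twofold, and five dipeptides from each class's reported top-10 list are
planted (positives: LL, LK, SL, IK, KR; negatives: DV, KG, DD, EF, GD).
Planting overwrites two adjacent positions rather than inserting, so
length distributions stay class-independent and cannot act as a
confounder. Lengths are uniform on 5–25 residues — typical of T-cell
assay epitopes; the source never states its length distribution — and
`effectSize` scales both the weight divergence (toward the two-class
midpoint) and the insertion probabilities, so `effectSize = 0` is an
exact null. Insertion probabilities are 0.3 (strong preset) and 0.15
(weak).

What the generator does *not* emulate: real epitope length/composition
correlations, positional motifs beyond planted dipeptides, homology
structure between peptides, or any binding/cytokine biology. Passing
tests therefore demonstrate that the pipeline recovers planted
compositional signal and behaves correctly at chance under the null —
not that any particular real-data AUC is attainable.

# Numerical choices and problem sizes

Sub-seeds for every stochastic stage are derived deterministically from
one master seed, so changing one stage's settings does not perturb
another's randomness; forests run single-threaded for run-to-run
reproducibility. Degenerate inputs fail loudly: constant labels, folds
exceeding class sizes, empty feature sets, single-class ROC input and
zero-variance AUC samples are all errors, and an all-identical score
vector tunes to cutoff 0.5 with a warning.

The test suite and the acceptance script exercise the protocol at
reduced, documented sizes chosen to keep the full run in minutes on one
CPU while leaving wide statistical margins: 250 + 250 peptides,
300–500-tree FIS forests over 3 folds, a 5-cutoff sweep and small
explicit grids. At these sizes the strong preset yields cross-validated
AUC ≈ 0.99 (threshold 0.8) and the null preset ≈ 0.47–0.53 (band
0.4–0.6). The full-scale defaults (10,000-tree FIS, 35-set sweep,
3,000-point forest grid, 10 × 5-fold CV) are what `runPipeline()` uses
when no reduced settings are passed.

# Known limitations

* The headline performance of the original AIP predictor is tied to its
  curated immunoassay dataset, which is not redistributable here;
  nothing in this package claims to reproduce those numbers.
* The greedy identity reduction is quadratic and intended for datasets
  of thousands, not millions, of peptides.
* SVM probability calibration (Platt) is refit per training fold and is
  itself stochastic in `libsvm`'s internal cross-validation only through
  the data order, which is fixed here; k-NN tie-breaking is seeded.
* Welch t-tests on sparse dipeptide frequencies are approximate for rare
  dipeptides; the null-calibration test quantifies how close the
  realized false-positive rate is to α at the shipped sample sizes.
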