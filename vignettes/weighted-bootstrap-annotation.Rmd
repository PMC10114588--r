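---
title: "Weighted bootstrap-annotation of cell types on imbalanced references"
author: "scLabelBoot"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weighted bootstrap-annotation of cell types on imbalanced references}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Cell type label transfer assigns labels to an unannotated (query) scRNA-seq
dataset using a pre-annotated (reference) dataset. Real references are
strongly imbalanced: in a typical PBMC atlas the common T cell subsets number
in the thousands while dendritic cells or megakaryocytes may number in the
tens. Most classifiers are trained or scored on the reference as-is, so rare
types are systematically under-recalled, and simply truncating every type to
the rarest type's size throws away most of the data and hurts the abundant
types instead.

`scLabelBoot` implements a weighted bootstrap-annotation scheme that keeps
both ends of this trade-off. For a reference with $K$ cell types of
abundances $n_1, \dots, n_K$ it draws one subset per type, where subset $j$
caps every type at $n_j$ cells (sampling uniformly without replacement;
types with fewer cells are kept whole). The subset capped at the largest
abundance is the full reference; the one capped at the rarest type's
abundance is fully balanced. Each subset is classified independently by any
of the package's label transfer algorithms, and a query cell's vote from
subset $j$ for label $l$ is weighted by

$$ w_{l,j} \;=\; \frac{1}{\lvert\, n(l) - \mathrm{cap}_j \,\rvert + 1}, $$

where $n(l)$ is the label's abundance in the *full* reference. A label
therefore votes at full weight exactly in the subset whose cap matches its
abundance — the subset in which it is best represented without being
overshadowed — and with rapidly decaying weight elsewhere. Weights are summed
per label over subsets (and over independent replicates of the whole series;
`nBoot`, default 20) and the argmax label is emitted, with the winner's share
of the total vote weight reported as a stability score.

A note on the weight's form: the defining expression without the absolute
value, $1/(n(l) - \mathrm{cap}_j + 1)$, is non-positive or undefined whenever
the predicted label is less abundant than the subset's cap, while the
surrounding logic requires a weight that is maximal when abundance and cap
agree and decays with their mismatch. The package therefore uses the
symmetric form above as its default; the literal asymmetric form is available
behind `strict = TRUE` in `computeWeight()` and errors on non-positive
denominators. On a perfectly balanced reference every weight is exactly 1 and
the scheme provably reduces to unweighted majority voting; the test suite
checks this reduction exactly.

Unassigned votes (from zero-signal cells or random-profile rejection, see
below) carry zero weight and can never win; a cell with only unassigned
votes stays unassigned.

## Preprocessing

All classifiers consume the same representation, built by `preprocessPair()`:

1. **HVG selection by analytic Pearson residuals.** Under a null model of
   constant relative expression, the expected count is
   $\mu_{cg} = \mathrm{rowsum}_c \cdot \mathrm{colsum}_g / \mathrm{total}$
   and the residual $r_{cg} = (x_{cg}-\mu_{cg}) / \sqrt{\mu_{cg} +
   \mu_{cg}^2/\theta}$, clipped to $\pm\sqrt{n_\mathrm{cells}}$ so a single
   outlier cell cannot dominate. Genes are ranked by residual variance
   (ties broken by gene id, making the ranking invariant to cell and gene
   order). $\theta$ is fixed at 100, the customary default for this
   selection method; it is exposed in the API. The default panel is 1000
   genes, with 200/1000/2000 as the conventional sweep.
2. **Log transform with additive pseudocount 0.001.** Note the convention:
   $\log(0 + 0.001) \approx -6.9$, *not* 0. Unlike the common `log1p`
   transform, a cell with no counts on the panel still carries a well-defined
   constant negative profile and is normalized like any other. This is a
   deliberate, documented choice; it makes "dropout" zeros informative
   rather than neutral.
3. **Cell-wise L2 normalization** to unit norm. Cells whose transformed
   profile is numerically all-zero (impossible under the default
   pseudocount, but reachable under other settings) are kept as zero
   vectors, flagged, and always predicted as `unassignedLabel()` rather
   than crashing a classifier.

HVGs are selected on the **reference alone** by default: that is where the
labels live, and selecting on the query risks leaking query structure into
the model. A `jointly = TRUE` flag selects on the concatenated pair instead.
For subset sweeps and the bootstrap, HVG selection happens once on the full
reference rather than per subset, so the experiments isolate the sampling
effect from gene-panel churn.

## The classifiers

The package ships lightweight, from-scratch implementations of four
label transfer algorithm families behind one contract
(`predictLabels(spec, reference, refLabels, query)`):

* **`centroid`** — per-type centroid of the processed reference; the query
  cell takes the label of the most Pearson-correlated centroid. Confidence
  is a softmax over centroid correlations (temperature `tau = 10`); two
  equidistant centroids give exactly 0.5. The fast baseline for sweeps.
* **`singler_like`** — iterative Spearman-correlation elimination. Per
  round: select discriminative genes among the surviving types (per type,
  the top `genesPerType = 50` genes by the difference between that type's
  median expression and the highest median among the other survivors; union
  over types); Spearman-correlate the query cell against every reference
  cell on those genes; aggregate per type as the 80th percentile of the
  per-cell correlations (`aggregate = "mean"` available); drop the
  lowest-scoring type **and** every type scoring more than `margin = 0.05`
  below the top — the margin applies to the raw aggregated correlations —
  until two types remain; predict the higher-scoring finalist. The
  confidence is artifact-defined (the underlying method publishes scores
  but no formula): $(s_1 - s_2)/(s_1 - s_\mathrm{min})$ clipped to $[0,1]$,
  with $s_\mathrm{min}$ the weakest first-round score, so a runaway winner
  scores near 1 and a photo-finish near 0.
* **`cca_mnn`** — canonical-correlation embedding plus mutual-nearest-
  neighbor voting. Both matrices are gene-standardized within dataset; the
  SVD of their cross-product embeds reference and query cells in a shared
  space (`nCca = 20` components, scaled by singular value so uninformative
  trailing components cannot dominate, then row-normalized); query cells
  take the majority label among their mutual nearest neighbors (`k = 5`,
  Euclidean), with confidence the winning vote share. Cells with no mutual
  partner fall back to their single nearest reference neighbor with
  confidence 0. The published method this emulates adds anchor weighting
  beyond the plain MNN vote; that refinement is intentionally out of scope.
* **`toppair_forest`** — top-pair transform plus random forest. Per type,
  genes are ranked by mean difference against the rest; the top
  `nTopGenes = 25` genes are each paired against every other type's best
  gene (deduplicated, capped at `maxPairs = 250`), and each cell becomes
  the binary vector $[x_{g_1} > x_{g_2}]$. A 200-tree random forest
  (`ranger`, fixed seed, single-threaded, inverse-frequency class weights
  so an imbalanced reference cannot let the forest's prior swallow the rare
  types) is trained on the encoded reference — in canonical (label, cell
  id) order, so the forest is invariant to reference cell order — and the
  confidence is the winning class's probability. Optionally `nRand` shuffled-expression pseudo-cells
  train an extra "none of the above" class; query cells classified there
  are emitted as `unassignedLabel()` and score as false predictions.
  `nRand = 0` (default) never emits unassigned labels.

Ties are broken by lexicographic label order everywhere — reproducibility
over elegance. All four classifiers are permutation-invariant in reference
cell order under a fixed seed; this is tested.

### A note on the batched elimination runner

The subset series multiplies the cost of the iterative Spearman classifier
by the number of subsets. Because a cell's within-cell ranks depend only on
the gene set — never on which other cells are in the subset — the bootstrap
runs all subset classifications as one batch: per elimination round, each
distinct surviving-type set has its rank matrix computed once and shared by
every run that needs it, and discriminative gene sets are derived from
full-reference medians so they agree across runs. A single run through the
batch is bit-identical to running it alone (tested); batching is purely a
scheduling choice.

## Reference design experiments

* `subsampleReference(dataset, cap, seed)` — per-type capped subsampling,
  with an independent RNG substream per (seed, type name) so adding a type
  never reshuffles another type's sample.
* `buildSubsetSeries(dataset, seed)` — the abundance-matched series that
  the bootstrap consumes.
* `sweepCaps(...)` — classify the query against capped subsamples over a
  cap grid (conventional preset 38, 100, 250, 500, 1000, 1500, 2000, 3000;
  20 permutations per cap by default, drawn independently per cap) and emit
  a tidy (cap, perm, cell_type, accuracy, precision, f1) table.
* `assembleMosaic(datasets, batchNames)` — concatenate multiple labelled
  sources into one reference **without any batch correction**, on the
  sorted intersection of their gene universes by default (union-with-zeros
  behind a flag; imputing zeros for genes a protocol never measured is the
  non-default for a reason). Cell ids are disambiguated as
  `"{batch}:{cell_id}"`; counts pass through bit-identically and per-type
  abundances add up across sources.

## Evaluation conventions

Per-type **accuracy** is recall/sensitivity — the fraction of that type's
query cells recovered. (In reference-design work the interesting trade-off
is recall versus precision per type; overall accuracy hides exactly the
rare-type failures at issue.) Precision is $TP_t/\#\{pred=t\}$, 0 for a
never-predicted type; F1 is their harmonic mean, 0 when both vanish. The
macro F1 is the unweighted mean over true types; because the aggregation
behind a single printed "overall F1" is ambiguous, the micro F1 (equal to
overall accuracy) is reported alongside. Unassigned predictions count
against their true type's recall and sit in a dedicated confusion column,
outside every type's precision denominator.

`boxplotStats()` uses linear-interpolation (type 7) quartiles — the
convention is configurable since none is canonical — with whiskers clamped
to the most extreme data inside $Q1 - 1.5\,IQR$ and $Q3 + 1.5\,IQR$ and
everything outside listed as outliers.

`confidenceCalibration()` splits each predicted type's confidences into
true and false groups and applies a two-sided Wilcoxon rank-sum test when
both groups have at least two members (the standard nonparametric
two-sample choice; the calibration question does not justify a parametric
form), flagging significance at $\alpha = 0.05$. No multiple-testing
correction is applied by default — per-type calibration calls are usually
read individually — but Benjamini–Hochberg is available via `adjust = "BH"`.

## The synthetic data generator

`generateSynthetic()` draws counts
$x_{gc} \sim \mathrm{NB}(\mu_{gc}, \theta_\mathrm{sim})$ with
$\mu_{gc} = s_c \, b_g \, f_{t(c),g} \, e_{b(c),g}$: a per-cell lognormal
library factor, a per-gene lognormal baseline, a marker fold for the cell's
own type, and a per-(batch, gene) multiplicative lognormal batch factor.
The master seed fixes the gene-level model (baselines, marker map, batch
factors), so a reference and a query drawn with different cell seeds share
the same biology — the precondition for meaningful label transfer.

Defaults, chosen once as realistic for PBMC-scale data and not revisited:
baseline mean $\mathrm{lognormal}(\log 0.5, 1.2)$ (mean count per gene of
order 1, heavy right tail), library sdlog 0.35, NB $\theta_\mathrm{sim} =
10$ (distinct from the preprocessing $\theta$; variance
$\mu + \mu^2/\theta$), marker fold 6 with 20 markers per type.

`presetPbmcLike()` encodes the working conditions of the package's own
experiments: 9 cell types at abundances 3000, 2500, 1500, 1000, 600, 300,
150, 60, 38 (9148 cells, ~80:1 imbalance, the rarest type at the smallest
conventional sweep cap), 2000 genes, and one closely related pair — the
rarest type shares half its markers with an abundant type, reproducing the
hard rare-type/abundant-type boundary that drives rare-type misprediction
in real PBMC annotations. `presetMosaic()` yields three sources sharing the
gene model but carrying independent batch effects (sdlog 0.3) and different
abundances, such that the rarest type's pooled abundance roughly triples
(38 → 102).

What the generator does *not* emulate: doublets, ambient RNA, explicit
dropout beyond NB sparsity, and continuous developmental trajectories.
Passing tests on these data therefore demonstrate correctness of the
machinery and the direction of sampling effects, not performance on the
messier boundaries of real tissue atlases.

## Problem sizes and numerical choices

The test suite and the acceptance script run at desk scale by design:
queries are drawn at one-twentieth of the reference abundances (floor 10
cells per type, ~475 query cells against the 9148-cell preset reference);
directional claims (rare-type rescue, cap-matching rule of thumb, mosaic
robustness) are averaged over 10 (or 5) fixed seeds with one subset-series
pass per bootstrap run — the direction of these effects does not require
the full 20 replicates, which remain the package default. The brute-force
oracle for the elimination loop is exercised on 100 random instances of up
to 4 types, 28 reference cells and 20 genes.

Other numerical choices: residual clipping at $\pm\sqrt{n_\mathrm{cells}}$
(exposed; `Inf` disables); rank ties averaged (matching
`cor(method = "spearman")`); quantile aggregation type 7; all stochastic
components seeded, with per-purpose substreams derived by hashing so
results are independent of call order; bootstrap replicate $r$ uses seed
$\mathrm{seed} + r - 1$.

## Known limitations

* The elimination loop's cost grows with the number of distinct surviving
  sets; on references beyond ~10⁴ cells with many similar types the
  `singler_like` bootstrap is minutes, not seconds, per run.
* `cca_mnn` stops at the plain MNN majority vote; no anchor scoring.
* The mosaic gene policy intersects gene universes; types distinguished
  only by genes missing from one source lose that signal.
* Confidence scores are method-specific and not calibrated probabilities;
  `confidenceCalibration()` exists precisely to audit them.
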