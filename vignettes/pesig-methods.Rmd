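---
title: "Pathway-extended gene signatures: models, parameters and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pathway-extended gene signatures: models, parameters and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pesig)
```

## The problem

Cell-line panels measure, for a given drug, both genome-wide expression
and a quantitative response — GI50, the concentration inhibiting growth
by half, handled here on a −log10 molar scale so that *larger* values
mean inhibition at *lower* concentration, i.e. sensitivity. Curated gene
lists for a drug are short and biased towards well-studied biology.
`pesig` implements a pipeline that (a) scores genes against GI50 by an
MFA correlation angle, (b) systematically widens the candidate pool to
pathway neighbours of correlating genes, (c) distils the pool into a
small Gaussian-kernel SVM signature by forward feature selection, and
(d) validates on an independent cohort, with MCC as the selection
metric and AUC-weighted ensembles on top.

## The correlation angle

For one gene with expression only, the angle is defined analytically:
$\theta = \arccos(r)$ for the Pearson correlation $r$ between the
gene's expression and GI50 across the panel, so $r = 1 \mapsto 0°$,
$r = -1 \mapsto 180°$, $r = 0.5 \mapsto 60°$. When copy number is
available, the gene's variables form one MFA group and GI50 the other:
all columns are standardized, each group is divided by its first
singular value (so no block dominates), the concatenated matrix is
decomposed by SVD, and every variable is placed on the correlation
circle by its correlations with the first two global score vectors. The
reported angle is the planar angle between a gene variable's position
and the GI50 position.

Two numerical decisions follow from this definition:

* **Dimensionality.** The angle is measured in the plane of the first
  two global dimensions. With at most three variables in play the plane
  captures the configuration essentially exactly, and the two-variable
  case provably collapses to $\arccos(r)$ — the package special-cases
  it and the test suite asserts the equivalence to $10^{-9}$ degrees
  over random vectors, plus sign symmetry
  ($x \mapsto -x \Rightarrow \theta \mapsto 180° - \theta$) and
  invariance under positive affine rescaling.
* **Degenerate inputs.** Constant expression, constant GI50, or fewer
  than three samples have no defined angle; such genes are skipped with
  a recorded reason rather than silently scored.

A gene *passes* at threshold $\theta_{\max}$ when
$\theta \le \theta_{\max}$ or $\theta \ge 180° - \theta_{\max}$ — both
directions of correlation are informative.

## Pathway expansion

Six conditions pair a maximum node distance (0, 1, 2) with a threshold
(10°, 20°). Expansion is a breadth-layered traversal: curated genes are
scored and filtered; the network neighbours of *passing* genes form the
next layer, minus genes already assigned a smaller distance; and so on
to the condition's depth. Three rules matter:

* failing genes are dead ends — recruitment never passes through them,
  and a failing curated gene is excluded from the qualified set (it
  stays in the audit table, labelled distance 0);
* a gene's node distance is the *minimum* distance at which it was
  recruited, and its parents are the passing previous-layer genes it
  shares an edge with, so every output row is independently checkable
  against the network;
* edges are undirected regardless of SIF interaction type — pathway
  adjacency is treated symmetrically.

Aliases are resolved (uppercased, mapped through the alias table) on
both the seed list and the network node names *before* traversal, and
the final parent–child list is re-verified against the network
(`verify_associations()`), returning removed pairs for audit. This
two-sided guard reproduces the failure mode it exists for: deprecated
aliases reassigned to unrelated genes create spurious associations that
no real edge supports. Genes whose copy number (but not expression)
correlates with GI50 pass the filter and are traversed through, but are
flagged ineligible as SVM features, since validation cohorts carry no
copy-number data.

The output is monotone in both dials — enlarging $\theta_{\max}$ or the
depth can only grow the qualified set — and the module is fully
deterministic; both properties are asserted over random fixtures, and
the dead-end rule is checked against an independently written BFS
oracle.

An optional per-gene neighbour cap (`max_neighbors`, off by default) is
provided for hub control on real interaction networks, where a single
hub can recruit thousands of candidates.

## Signature derivation

GI50 is dichotomized at the median; when two or more lines tie the
median exactly, the median no longer yields a clean split and the
threshold moves to the observed value whose gap to the next larger
sorted value is widest, with the tied block falling on the resistant
side (the rule exists to separate the tied block from the clearly
sensitive upper tail). Samples exactly at a unique median are called
sensitive under the default polarity (`≥` threshold). Polarity is
exposed (`high_value_sensitive` by default) because response scales
differ in direction across sources. A constant GI50 vector is a hard
error: no split exists.

The SVM uses the Gaussian kernel
$K(u, v) = \exp(-\lVert u - v \rVert^2 / \sigma^2)$ (the kernel-scale
convention, i.e. $\gamma = 1/\sigma^2$), features standardized by
training-panel mean and SD. The hyperparameter grid is
$C, \sigma \in \{1, 10, \dots, 10^5\}$ with $C \ge \sigma$: 21 pairs.
Forward feature selection evaluates, each round, every remaining
candidate appended to the current list by stratified k-fold
cross-validation and accepts the best candidate only on *strict*
improvement (tolerance 0 by default, configurable). Design choices:

* **k = 5 stratified folds.** The fold count is not dictated by the
  method; 5 keeps at least a handful of samples per class per fold at
  panel sizes near 48. It is exposed as a parameter. Fold assignment is
  deterministic given the seed (per-class shuffle, round-robin deal).
* **Randomized candidate order.** Candidates are shuffled each round
  under the run seed; ties on the criterion are broken in favour of the
  first-encountered candidate. Fixed seed therefore means byte-identical
  signatures, which the suite asserts.
* **Log loss needs probabilities.** A margin classifier emits none, so
  a logistic (Platt-style) map from decision value to class probability
  is fitted on each fold's training portion and applied to the held-out
  fold, with probabilities clipped to $[10^{-15}, 1 - 10^{-15}]$ so a
  separable fold cannot produce an infinite loss.
* **Class encoding.** Resistant is the positive class (+1) throughout —
  MCC sign, AUC orientation and the ensemble's +1 vote all follow it.
* **Two-gene floor.** Pathway-extended runs whose selection stops at one
  gene are excluded from validation (kept in an audit list); the point
  of extension is multi-gene signatures. Curated-only runs are exempt.

The trained decision function is stored in portable parameters (support
vectors, coefficients, offset, feature centring/scaling) and written as
versioned plain text at full double precision, so a round-tripped model
reproduces predictions bit-for-bit; truncated or foreign files fail
with integrity errors.

## Validation, importance and ensembles

Validation cohorts are probe-collapsed (per-sample mean over probes
sharing a symbol) and quantile-normalized *onto the training panel's
mean-quantile vector*, not self-normalized: the decision function is
calibrated on training-scale values, so the cohort must be mapped to
that scale. Self-referenced normalization remains available, and a
length-mismatched reference is an error unless interpolation through
quantiles is explicitly enabled. Ties within a sample receive the mean
of the implicated reference quantiles, so ranks are preserved exactly.

Scoring reports confusion counts, per-class and overall accuracy, MCC
(zero-denominator convention: 0 — the common choice for degenerate
single-class predictions) and midrank AUC. Model selection maximizes
MCC because the cohorts of interest are imbalanced; ties break by
higher overall accuracy, then by fewer genes. Display rounding follows
reporting convention (percentages to the nearest integer, MCC to two
decimals). Leave-one-gene-out importance retrains at the model's
(C, σ) without each feature in turn and reports the criterion and
test-metric deltas; a gene whose removal *raises* test MCC is flagged a
candidate machine-learning false positive.

Ensembles weight each member's ±1 vote by its cohort AUC; the sign of
the weighted sum decides. An exactly-zero sum is called resistant with
a warning — defining only the strict inequalities leaves the tie open,
and a non-response call is the conservative clinical default. A sample
is a consensus call when at least 75% of members agree (the threshold
is configurable). Note the AUC weights are computed on the same cohort
being predicted, which is optimistic; with truly independent data a
held-out weighting cohort is preferable.

## What the synthetic generator emulates — and what it does not

`synthetic_spec()` defaults define the reference study conditions:

| parameter | default | rationale |
|---|---|---|
| `n_cell_lines` | 48 | realistic training-panel size; keeps angle noise representative |
| `gi50_range` | 3.0–6.5 | plausible −log10 molar span for kinase inhibitors |
| `n_genes` | 60 | desk-scale universe: 8 planted + 2 CN-only + 50 noise |
| `planted_r` | 0.95 | planted angle 18.2°, inside the 20° but outside the 10° conditions |
| `edge_density` | 0.02 | sparse background so traversal is governed by the angle filter |
| `n_patients`, `imbalance` | 40, 1:3 | echoes the size and skew of real validation cohorts |
| `effect_size` | 2 SD | clearly separable but noisy patient classes |
| `probe_dup_fraction` | 0.3 | exercises probe collapsing on a realistic fraction |

Two generator design decisions deserve emphasis because tests depend on
them:

* **Exact in-sample planting.** Planted genes mix the standardized GI50
  vector with noise *residualized against it*, so the realized sample
  correlation equals ±`planted_r` exactly, not merely in expectation,
  and the planted angle is deterministic. Had the correlation only held
  in expectation, sampling noise at n = 48 would push each planted gene
  below the 20° threshold in roughly a quarter of draws (Fisher-z
  arithmetic), and near-complete recovery of planted chains would not be
  a meaningful expectation at these panel sizes.
* **Shared gene baselines.** The panel and the patient cohort draw each
  gene's baseline mean from one gene-keyed stream: the generator
  emulates cohorts already calibrated at the gene level, leaving
  quantile normalization to absorb sample-level distribution shifts.
  Real cross-platform cohorts additionally carry gene-level offsets that
  quantile normalization does not remove; the generator deliberately
  excludes that failure mode, so passing tests demonstrate correct
  pipeline mechanics, *not* robustness to platform-specific gene-level
  bias.

The generator also omits realistic microarray noise structure
(intensity-dependent variance, batch effects) and any correlation
structure among noise genes. Null behaviour: with `effect_size = 0` the
cohort carries no class signal, and a signature trained on a *balanced*
panel has no mechanism to prefer the cohort's majority class — its
expected agreement with 1:3-imbalanced truth sits near 50%, below the
75% majority-class baseline. The null tests therefore assert collapse
to *no better than* the naive baseline rather than equality with it.

## Problem sizes used in the checks

The end-to-end checks run preselection recovery on 20 seeded replicates
of the default study, and full grid derivation plus cohort validation
on 3 replicates, with the seed-mean as the reported statistic; the
remaining property suites use panels of 12–60 samples and pools of up
to 20 genes. These sizes were chosen to make the planted structure's
recovery statistically unambiguous while keeping the whole suite quick
to run.

## Known limitations

* Per-gene MFA (gene variables + GI50) matches the expansion loop's
  gene-at-a-time design; it is not a global MFA over all genes, and no
  qualitative-group or partial-axes machinery is provided.
* The SVM is a plain two-class margin classifier; multiclass reduction
  schemes are out of scope.
* AUC-weighted ensembles fitted and evaluated on the same cohort
  overstate independent performance (flagged above).
* The alias table is whatever the user supplies; no live nomenclature
  service is queried.
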