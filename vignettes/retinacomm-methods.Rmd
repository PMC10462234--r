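---
title: "Methods: loop-aware ligand-receptor scoring and differential communication toward surviving RGC subclasses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: loop-aware ligand-receptor scoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(retinacomm)
```

# The scientific question

Retinal ganglion cell (RGC) subclasses differ sharply in how well they
survive optic nerve injury. If part of that resilience is conferred by
signals from the surrounding retina — Müller glia, astrocytes, microglia,
amacrine, bipolar and photoreceptor cells — then the ligand–receptor
interactions pointing at the resilient subclasses should be measurably
stronger than those pointing at the vulnerable ones. `retinacomm` turns
that idea into a pipeline: score communication per (sender, receiver,
pair, time point), stabilise the scores with feedback-loop evidence,
filter to credible interactions, and contrast high- versus low-survival
receivers.

# Interaction scoring

## Base score

For a pair (L, R), the base score at one time point is the geometric mean
`sqrt(ℓ · r)` of two scaled expression summaries: ℓ is the mean
normalized expression of the ligand in the sender group, r of the
receptor in the receiver group. Normalization is counts-per-10k followed
by `log1p` throughout the package; nothing downstream sees raw counts.

Each gene's group means are min–max scaled to [0, 1] across **all**
(cell group, time point) means of the dataset. This makes the score a
relative-strength measure — 1 means "this group, at this time, is where
this gene is strongest" — and gives the fixed 0.5 score cutoff a
meaningful interpretation on any dataset. Two consequences are worth
knowing:

* a ligand absent from a sender at all time points scores exactly 0;
* a gene whose group means are all identical has no between-group
  contrast and is defined to scale to 0 (it cannot distinguish any pair
  of groups, so it should not generate interaction signal).

## Feedback loops

A forward interaction (L₁ from the sender, R₁ on the receiver) gains
support when the receiver can "answer": receptor signalling reaches a
back ligand L₂ through the receiver's own signalling/regulatory network
(a directed path R₁ → … → L₂ of at most `max_path_len = 4` edges —
receptor → signalling → transcription factor → ligand), and the back
receptor R₂ is expressed on the original sender. Path queries run on the
**active subgraph** of each cell type: only edges whose both endpoint
genes are detected in ≥ 10 % of that type's cells. The default path
length of 4 reflects the short relay chains such loops realistically
take; a sender-side return path R₂ → … → L₁ is recorded as extra
evidence when present but is not required.

The adjustment is multiplicative and capped:

`S_LR = min(1, s0 · (1 + β · B))`,

where B is the strongest back-pair base score among the detected loops
(`max`; switching to `sum` is exposed as a parameter but max is the
default, since one strong loop is qualitatively different from many weak
ones) and β defaults to 0.5. The form is monotone in β and in the back
scores, reduces exactly to the base score when β = 0 or no loop exists,
and keeps scores in [0, 1] so the 0.5 filter stays interpretable.

## Filtering

A (sender, receiver, pair) key survives when

1. the ligand is detected (count > 0) in ≥ 10 % of the sender's cells
   and the receptor in ≥ 10 % of the receiver's cells, and
2. its score reaches ≥ 0.5 at some time point (boundary inclusive:
   a trajectory whose maximum is exactly 0.5 is kept).

Detection rates are stored per (group, time point); the 10 % rule uses
the maximum over time points, on the reasoning that a pair detectable at
any sampled time can act then. All time points of surviving keys are
retained, and the filter is idempotent. The overall communication
strength between two cell groups at a time point is the plain sum of
surviving pair scores.

Groups smaller than 10 cells are scored but flagged low-confidence
rather than dropped: tiny subclasses are common in real subclass-level
analyses and silently losing them is worse than flagging them.

# Differential interactions between survival classes

For each sender and pair, every receiver subclass contributes its
maximum score over time points; these maxima are averaged within the
high-survival set and within the low-survival set, and

`D_SLR = mean(high maxima) − mean(low maxima)`.

Calls use strict cutoffs: protective above 0.25, depleted below −0.25,
ties at exactly ±0.25 neutral. The statistic is antisymmetric under
swapping the two sets, and zero for any fully exchangeable score table.
The max-over-time uses all four time points, including the pre-injury
one, matching the statistic's definition; restricting to post-injury
times is a caller-side subset if ever needed.

Pair selection and the differential run at different granularities, as a
practitioner would do it: pairs are first filtered with all RGC
subclasses pooled as one receiver type (stable detection rates), then
the surviving pairs are scored per subclass for `D_SLR`. Computing the
differential directly on a subclass-filtered table would silently drop
any pair that fails the 0.5 cutoff in even one vulnerable subclass —
exactly the pairs the statistic is about.

The non-redundant aggregate deduplicates records by (ligand, receptor),
keeps the best D_SLR across senders, and ranks by that value with ties
broken by the number of supporting senders and then lexicographically.
The ranking rule is this package's choice; nothing in the underlying
analysis prescribes one.

# Dynamics

* **Variable interactions**: a trajectory is variable when
  `(s_i + c) / (s_j + c) > 1.2` for some ordered pair of time points.
  The pseudocount c = 0.05 (on the [0, 1] score scale) keeps ratios of
  near-zero scores from exploding; the fold change is computed on raw
  scores, not z-scores.
* **Temporal groups**: z-scored trajectories, correlation distance,
  average-linkage hierarchical clustering cut at k = 4. Chosen for
  determinism and shape (not level) sensitivity. Constant trajectories
  are rejected rather than silently placed — filter for variability
  first.
* **Preset vs induced**: `pre_diff` is the high-minus-low difference at
  the pre-injury time point, `post_diff` the same difference of maxima
  over post-injury times. Preset if `pre_diff > δ`, induced if
  `pre_diff ≤ δ < post_diff`, else neither. δ defaults to 0.25 for
  consistency with the protective cutoff; no separate threshold is
  published for this classification.

# Survival-normalized composition

Within-sample subclass percentages are not comparable between conditions
with different overall survival, so they are scaled by an externally
measured total survival rate (e.g. 63.8 % for injured controls, 85.4 %
under neuroprotective treatment, 1.0 for sham):
`adjusted_i = pct_i × rate`. Adjusted percentages sum to `rate × 100`
and between-subclass ratios are unchanged. Survival rates are inputs,
never inferred from the expression matrix — they come from counting
surviving cells in tissue, which is outside this package's contract.

# FISH dot quantification

Discrete signal dots are 8-connected components of pixels at or above a
detection threshold (8-connectivity so diagonal-touching pixels form one
dot). Calibration on a representative region of roughly 20 dots gives

`avg per dot = (Σ integrated dot intensity − background × Σ dot area) / n dots`,

and a region's total dot number is

`(total intensity − background × area) / avg per dot`.

When not supplied, the threshold defaults to background mean + 3
background SD and the background to the mean of below-threshold pixels;
on a constant (noise-free) background the default threshold degenerates
to the background itself, so thresholds should be set explicitly for
synthetic noiseless images. Both formulas are exact on such images:
planted fields are recovered to the planted count.

# The synthetic study conditions

The generator's defaults define the conditions every end-to-end test and
the acceptance script run under, chosen once to mirror the target
design at desk scale:

* 6 sender types and 6 RGC subclasses — ipRGC, alphaRGC, Gpr88RGC as the
  high-survival set, three generic vulnerable subclasses as the low set;
* 4 time points (sham, 12 h, 24 h, 48 h), 60 cells per (group, time
  point) — 2,880 cells, 600 genes;
* negative-binomial counts (mean 2.5, size 2) with lognormal library
  factors (sdlog 0.3, mean 1), 5 marker genes per label boosted 8×,
  2 % mitochondrial genes ("mt-" prefix) with 5 % of cells mito-inflated
  25× to exercise the QC filter;
* generic genes get a lognormal per-major-type multiplier (sdlog 1.25 —
  strongly type-restricted expression, as ligands and receptors are in
  real tissue), small per-subclass jitter (sdlog 0.1, subclasses of one
  type share most of their transcriptome) and per-time-point jitter
  (sdlog 0.15);
* 6 planted pairs (3 preset, 3 induced; effect 4; receptor boost
  targeted at the high-survival subclasses; flat baseline so the boost
  is the only group structure), 2 planted feedback loops with their
  relay edges and back pairs in the ground-truth network and pair table,
  plus 50 decoy pairs.

What this emulates: overdispersed counts, library-size spread, genuine
type-specific expression, marker structure, high-targeted protective
signal with preset/induced dynamics, loop relays. What it does not:
doublets, ambient RNA, batch effects, dropout beyond NB sampling,
realistic gene names, or subclass-specific injury responses in the
background transcriptome. Passing the recovery tests therefore shows the
pipeline's statistics behave as designed under their own assumptions; it
does not certify performance on real atlases, where the QC presets,
detection thresholds and cutoffs all interact with far messier signal.

A scale caveat: `log10GenesPerUMI = log10(nGene)/log10(nUMI)` depends
structurally on the gene-universe size, and a 600-gene universe cannot
reach the values a 20,000-gene transcriptome produces. The published
absolute QC presets (`qc_preset("whole_retina")` etc.) are therefore
intended for real data; the pipeline's default applies the gene-breadth
filter but no absolute cell preset when running on synthetic atlases,
and the QC rules themselves are verified against independent per-cell
rule evaluation on fixtures built to violate each rule at the published
thresholds.

# Numerical and degeneracy choices

* QC boundary semantics are literal: removal conditions are strict
  inequalities, so a cell with nUMI exactly 800 under the whole-retina
  preset stays. Cells with nUMI ≤ 1 have undefined complexity and are
  removed by any filter.
* Marker assignment ties break to the lexicographically first type name;
  the winning margin is recorded per cell.
* Loop witness paths are shortest, ties broken lexicographically; loop
  sets are invariant to edge insertion order. A back ligand identical to
  the forward receptor is never reported (the relay path must be a
  non-empty simple path).
* Empty score tables, empty loop sets and empty differential tables are
  valid and propagate as empty results, not errors; missing subclass
  scores and missing pre-injury time points are errors, since silently
  averaging over an incomplete panel would bias D_SLR.
* All stochastic stages consume a single seed; the pipeline writes a
  manifest with md5 hashes, and identical configs give byte-identical
  artifacts.

# Problem sizes

Default test and acceptance runs use the 2,880-cell atlas above, 20
independent seeds for recovery statistics, 200 random ≤ 8-node graphs
for loop-oracle equivalence, and 128×128 images with 20–25 planted dots.
These sizes were chosen so the whole suite exercises every statistic at
meaningful replication while staying comfortable to run interactively.

# Known limitations

* The base-score functional form (geometric mean of min–max-scaled group
  means) is this package's fixed choice among the family consistent with
  "expression of ligand in sender, receptor in receiver"; other
  published scorers (product, truncated mean, permutation-based) will
  rank borderline pairs differently.
* Min–max scaling is dataset-relative: scores are not comparable across
  datasets without a shared scaling population.
* Loop evidence uses one combined back score per pair; pathway-weighted
  diffusion or ligand-activity regression are out of scope.
* No statistical significance is attached to individual pairs; the
  cutoffs are fixed effect-size thresholds, not error-rate guarantees.
* Cluster assignments from average-linkage trees can be sensitive to
  near-tie merge heights; with the planted four-shape structure they are
  stable, but k should be treated as exploratory on real trajectories.
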